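# picaco

**PIC-seeded ant colony optimization for microsatellite marker panel
reduction.**

Microsatellite (SSR) surveys in conservation genetics and breeding often
genotype 20-30 codominant loci. `picaco` finds a smaller panel whose
**average Nei genetic distance (AGD)** between populations (or
individuals) stays within a chosen *accuracy-loss margin* of the full
panel's AGD, so population-genetic conclusions survive the cost cut.

Panel selection is treated as a combinatorial search over binary
inclusion vectors $I = [i_1, \dots, i_k]$. The cost of a panel is

$$f(I) = 100 \cdot \frac{|AGD(I) - AGD(\mathrm{full})|}{AGD(\mathrm{full})}\ \ [\%],$$

where the pairwise distance restricted to a panel is Nei's standard
distance

$$D_{a,b} = -\ln \frac{\sum_k \sum_j p_{ajk} p_{bjk}}{\sqrt{\sum_k \sum_j p_{ajk}^2 \cdot \sum_k \sum_j p_{bjk}^2}}.$$

The core search is an ant colony optimizer (50 ants, 120 epochs,
pheromone weight $\alpha = 0.7$, retention 0.9) on a graph with one
include and one exclude node per locus. Its distinguishing feature is
**PIC seeding**: initial pheromones are set from each locus's polymorphic
information content ($\tau_{in} = \varepsilon + PIC_j$), so the search
starts in the informative region of panel space and typically reaches its
global best within the first epochs, several times faster than
random initialisation. Four schemes sit behind one interface: `pic_aco`,
`aco`, `pic` (rank prefix), `random` (control), plus an exhaustive oracle
for $k \le 20$.

The package also provides per-locus diversity statistics (Na, Nea,
AR = Na/individuals, Botstein PIC, Ho, He), GenAlEx and long-CSV
input/output, Tukey-HSD scheme comparison, full-versus-reduced panel
discrepancy reports with significance tiers, a Balding-Nichols genotype
simulator, and a command-line front-end (`inst/cli/picaco`) with
`stats`, `distance`, `select`, `compare`, `evaluate` and `simulate`
subcommands.

## Worked example

Simulate a structured survey (4 populations x 30 individuals, 10
multi-allelic loci), inspect the markers, and ask for the smallest panel
within a 5% accuracy-loss margin:

```r
library(picaco)

g <- simulate_genotypes(n_pops = 4, n_per_pop = 30, n_loci = 10, seed = 2026)
locus_stats(g)
#> # A tibble: 10 × 8
#>    locus    Na   Nea     AR   PIC    Ho    He n_obs
#>  1 L01      13  6.95 0.108  0.841 0.707 0.856   116
#>  2 L02      14  7.57 0.117  0.855 0.739 0.868   119
#>  3 L03      16  6.46 0.133  0.829 0.744 0.845   117
#>  ...
#> 10 L10      15  8.93 0.125  0.878 0.765 0.888   119

fit <- pic_aco_select(g, margin = 5, seed = 1)
fit
#> # panel_selection: scheme pic_aco (margin mode)
#> #   2 of 10 loci, accuracy loss 3.719% (AGD reference 0.7644)
#> #   panel: L03, L04
```

Two loci out of ten already reproduce the full-panel AGD (0.764) to
within 3.7% on this synthetic survey -- the margin-mode scan walked down
from 9 loci and stopped at the smallest qualifying size. `glance(fit)`
returns the run as a one-row tibble (scheme, mode, n, loss, accuracy,
epochs to best, seed); `tidy(fit)` gives one row per locus with its
inclusion flag; `autoplot(fit)` draws the convergence trace.

How distorted are the diversity statistics on the reduced panel?

```r
panel_discrepancy(g, fit$panel)
#> # A tibble: 6 × 8
#>   statistic mean_panel mean_full mean_diff  fold  t_stat p_value significance
#> 1 Na            14        12.3      1.7    1.14   0.748    0.472 ns
#> 2 Nea            6.35      6.46    -0.114  0.982 -0.0910   0.929 ns
#> 3 AR             0.117     0.103    0.0142 1.14   0.748    0.472 ns
#> 4 PIC            0.826     0.813    0.0131 1.02   0.256    0.803 ns
#> 5 Ho             0.740     0.722    0.0187 1.03   0.582    0.573 ns
#> 6 He             0.842     0.831    0.0114 1.01   0.251    0.807 ns
```

No statistic shifts significantly (`ns` throughout), and the AR and Na
fold changes coincide by construction (AR = Na/individuals). Scheme
comparison across sizes, with Tukey contrasts and boxplots:

```r
cmp <- compare_schemes(g, n_values = 3:6, replicates = 10, seed = 1)
glance(cmp)    # best scheme per panel size
autoplot(cmp)  # accuracy boxplots
```

The same operations are available from a shell:

```sh
Rscript inst/cli/picaco simulate --out sim --n-pops 4 --n-per-pop 30 --seed 2026
Rscript inst/cli/picaco select --in sim/genotypes.csv --out sel \
    --scheme pic-aco --margin 5 --seed 1
cat sel/panel.txt
```

Every output directory contains a `manifest.json` (parameters, input
digest, seed, version) sufficient to re-run the command.

## Vignette

`vignettes/marker-panel-optimization.Rmd` documents the model and its
assumptions, the optimizer's parameters and update rule, the margin-mode
semantics, what the simulator does and does not emulate, and the
construction of the planted test instance.
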