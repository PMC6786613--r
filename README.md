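# herdnet

Agent-based simulation of wealth inequality and patron-client network
formation among nomadic pastoral households.

## The problem

In extensive herding economies, households privately own animals but graze
them on communal pasture. Environmental disasters (droughts, snowstorms,
disease) strike households differentially, and the pasture's total biomass
caps how many animals the system can carry. `herdnet` asks how these two
environmental variables — **carrying capacity** and **disaster risk** —
shape the emergence of wealth inequality and of hierarchical support
networks, in which wealthy patrons transfer animals to impoverished
client households. The package is aimed at researchers in human ecology,
archaeology and socio-ecological modelling who want a fast, fully
reproducible reimplementation of this model family with a tested R API
and a command-line interface.

## The model

Each of *n* households (default 100) starts with 60 animals. Per time step
(≈ one year, 2,000 steps per run), in order:

1. **Growth** — visiting households in random order, each grows its herd
   by rate *g* (10%) iff the system total *T* is still below carrying
   capacity *K* at its visiting moment (`T` is re-read before every
   grant, so the wealthy can exhaust the headroom first);
2. **Disasters** — each household independently loses fraction *s* (50%)
   of its herd with probability *p* (5–20%);
3. **Poverty resolution** — households with herd < 60 receive 60 animals
   from their patron, or link to a random household with herd > 800; if
   none exists and herd < 2, the household dies;
4. **Patron floor** — patrons with herd < 500 lose their clients.

Recorded per run: the Gini index of herd wealth
*G* = Σᵢⱼ|xᵢ−xⱼ| / (2n²x̄), the largest number of clients any patron held
simultaneously, the duration (consecutive steps) that the run-maximal
network stayed the largest, and the end population. The expected herd
multiplier per step is (1+g)(1−ps): with g = 10% and s = 50%, risk
p = 20% puts average losses equal to average growth, the boundary below
which accumulation — and hence patronage — is possible.

Two engines implement the identical model: optimized C++ and a naive
loop-per-agent R reference, bit-identical for any seed (the test suite
enforces this). See `vignette("herd-networks")` for the full method
account and design choices.

## Worked example

```r
library(herdnet)

p <- sim_params(carrying_capacity = 50000, disaster_prob = 0.10)
run_simulation(p, seed = 42)
#> # A tibble: 1 × 5
#>    seed final_gini largest_network_size largest_network_duration end_population
#>   <int>      <dbl>                <int>                    <int>          <int>
#> 1    42      0.617                   76                      284            100
```

One run at a rich, moderately risky setting: final wealth Gini 0.617
(substantial inequality), a patron who at peak simultaneously supported
76 of the other 99 households, a 284-step reign as the largest network,
and no household deaths.

```r
sw <- run_sweep(capacities = c(10000, 30000, 50000),
                disaster_probs = c(0.05, 0.15), n_runs = 20, base_seed = 1)
summarize_sweep(sw)
#> # A tibble: 6 × 7
#>   carrying_capacity disaster_prob n_runs mean_gini mean_network_size
#>               <dbl>         <dbl>  <int>     <dbl>             <dbl>
#> 1             10000          0.05     20     0.420              16
#> 2             10000          0.15     20     0.397              20.4
#> 3             30000          0.05     20     0.480              61.6
#> 4             30000          0.15     20     0.491              68.5
#> 5             50000          0.05     20     0.633              74.6
#> 6             50000          0.15     20     0.610              81.7
```

Mean largest-network size rises steeply with carrying capacity at every
risk level — the model's central result. `plot_sweep(sw)` draws the
trend; `standardized_ols(sw, "largest_network_size",
c("carrying_capacity", "disaster_prob"))` quantifies it with standardized
betas (`tidy()`/`glance()` methods included), and
`capacity_shift_run()` implements the experiment in which capacity is
raised mid-run once a burgeoning network reaches a trigger size.

## Command line

```sh
inst/cli/herdnet sweep --runs 100 --seed 1 --out results/
inst/cli/herdnet gini-sweep --runs 100 --no-networks --no-deaths --out results/
inst/cli/herdnet shift --runs 20 --low-capacity 10000 --high-capacity 50000 --trigger 20
inst/cli/herdnet regress --runs 100 --out results/
```

Subcommands: `run`, `sweep`, `gini-sweep`, `shift`, `regress`. Flags
mirror `sim_params()`; YAML/JSON config files are supported via
`--config` (precedence: defaults < file < flags). Results are written as
CSV (per-run table, per-combination means, regression summaries) plus a
`metadata.json` that suffices to regenerate every row bit-exactly.

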