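# fluorosim

Monte Carlo simulation of single-molecule peptide **fluorosequencing** —
sequencing peptides by selectively fluorescent-labeling a few amino acid
types, anchoring each molecule to an imaging surface, and watching
per-channel luminosity drops as Edman degradation removes one N-terminal
residue per cycle. The observed drop pattern (the *fluorosequence*, e.g.
`WKKxY`) is a partial positional read that can identify its source protein
against a reference proteome.

The package is for proteomics researchers and method developers who want to
ask, before building an instrument: *how much of a proteome could this
read-out identify, and how badly do the realistic failure modes hurt?* It
provides:

* in-silico proteolysis (GluC, CNBr, trypsin, none, custom rules), anchor
  filtering (cysteine / C-terminus) and digest statistics;
* deterministic ideal-read encoding and analytic coverage curves;
* the three stochastic error models — per-label dye failure (Bernoulli
  *u*), Edman cycle inefficiency (inter-label interval *d* takes *d + e*
  cycles with negative-binomial *e*: P(e) = C(d−1+e, e) p^d q^e), and
  exponential photobleaching (survival e^(−bk), b = ln2 / half-life);
* a prefix-trie attribution engine: per-read, per-source-protein counts,
  empirical posteriors P(protein | read), unique-attribution thresholds
  (count ≥ 10 per 10,000 copies and rivals < 10%), and proteome coverage;
* reproducible Monte Carlo drivers: `run_monte_carlo()`,
  `parameter_sweep()`, shard-invariant seeding, a synthetic-proteome
  generator so nothing needs downloading, and a thin CLI
  (`inst/cli/fluorosim.R`).

## Worked example

Simulate a 50-protein synthetic proteome (human-like residue frequencies),
GluC-digested, cysteine-anchored, two labels (Lys, Tyr), with realistic
errors — 15% dye failure, 94% Edman efficiency, 1800-cycle photobleach
half-life — at 200 copies per peptide:

```r
library(fluorosim)

prot <- generate_synthetic_proteome(50, composition = composition_human(), seed = 1)
cfg <- simulation_config(prot, "gluc", "cysteine", "K+Y", cycles = 30,
                         depth = 200, seed = 11,
                         params = error_params(0.15, 0.94, 1800))
res <- run_monte_carlo(cfg)
res
#> <fluorosim_result> gluc + cysteine + K+Y, 30 cycles, depth 200 (scaled-down), seed 11
#>   271 peptides simulated; 54200 reads; coverage 80.0% (40/50 proteins)
```

So 271 Cys-containing peptides produced 54,200 simulated reads, and 40 of
the 50 proteins own at least one read uniquely attributable to them (80%
coverage) despite the error load. `tidy(res)` lists the uniquely attributed
reads; `glance(res)` gives the one-row run summary. The empirical posterior
at any observed read shows how confidently it points home — here a short,
heavily shared read:

```r
pmf_at(res$trie, "(K,2)")
#> # A tibble: 27 × 3
#>    protein_id count probability
#>  1 SYN000022    306      0.241
#>  2 SYN000019    162      0.128
#>  3 SYN000013    157      0.124
#> # … 24 more rows
```

Twenty-seven rival proteins yield `(K,2)`, so it identifies nothing — while
most longer reads have a single dominant source. `autoplot()` methods plot
coverage curves, digest histograms, attribution posteriors, and sweep
results; `ideal_coverage_curve()` gives the deterministic zero-error
ceiling, and `parameter_sweep()` maps coverage over the three error axes.

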