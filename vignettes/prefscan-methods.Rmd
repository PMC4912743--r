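---
title: "Methods: screening amino-acid preferences against descriptor scales"
author: "prefscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening amino-acid preferences against descriptor scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefscan)
```

## The question the package answers

Deep mutational scanning of a saturated mutant library, or a large alignment
of homologous sequences, assigns every site $j$ of a protein a distribution of
preferences over the 20 amino acids. At many sites that distribution is not
arbitrary: it tracks a simple property of the amino acids — buried sites favor
hydrophobic residues, tightly packed sites favor small ones, hinge regions
favor flexible ones. `prefscan` makes that observation quantitative: for each
site it asks whether the preferences are a (noisy) linear, optionally
quadratic, function of an amino-acid *descriptor scale*, and reports which
descriptor explains each site best, under family-wise control of false
positives.

## Input metrics and the free-energy encoding

A preference can be any per-amino-acid metric that increases monotonically
with the probability of observing that amino acid at the site
(`metric = "preference"`). Alignment columns are instead encoded as
*statistical free energies*: with pseudocounted column counts $c_{i,j}$,

$$\Delta\Delta G_{i,j} \;=\; -\log_{10}\frac{c_{i,j} + \lambda}{c_{wt,j} + \lambda},$$

so the query (wild-type) amino acid sits at exactly 0 and disfavored amino
acids are positive (`metric = "ddg"`, built by `alignment_to_ddg()`). Before
fitting, responses are oriented so that *higher always means more favored*:
free energies are negated, preference metrics pass through unchanged
(`response_values()`).

Decisions taken where the interface was genuinely open:

* **Pseudocount** $\lambda$: add-one (Laplace) per amino acid per column by
  default, exposed as a parameter. It is the simplest standard choice and
  guarantees finite free energies even when the wild type is absent from a
  column.
* **Query counting**: the query sequence is a member of its own alignment and
  is counted in the column totals. A column of $N$ records all carrying the
  wild type therefore yields $\Delta\Delta G = \log_{10}((N+\lambda)/\lambda)$
  for every other amino acid.
* **Coordinates**: residue numbers from alignments are 1-based ungapped query
  positions; an `offset` maps them onto author/PDB numbering. No automatic
  sequence-to-structure alignment is attempted — reconciliation is explicit.
* **Non-canonical letters** (B, Z, X, U, O) and gaps (`-`, `.`) are excluded
  from counts and tallied per column (`n_excluded`); a column where every
  non-query row is a gap is emitted with a `low_coverage` flag rather than
  dropped.

## Tolerance to substitution

Each site is summarized by the *effective number of tolerated amino acids*

$$k^\* \;=\; 2^{H},\qquad H = -\sum_{i=1}^{20} f_i \log_2 f_i,$$

the base-2 perplexity of the site's amino-acid frequencies $f_i$. This is the
only definition consistent with the metric's intended range: a single
tolerated amino acid gives $k^\*=1$, a uniform distribution gives $k^\*=20$,
and two amino acids at 0.5 give exactly 2. For `ddg` inputs the frequencies
are recovered as $P_i = 10^{-\Delta\Delta G_i}$ (so $P_{wt}=1$) and
normalized; for preference inputs the non-negative preferences are normalized
directly, which makes $k^\*$ invariant to overall scaling of the input. A
user-supplied $k^\*$ column is honored verbatim and never recomputed.

## The descriptor catalog

Thirty descriptor scales in four sets, scanned in set order:

* **Set 1** (8): volume, log(solubility), hydrophobicity, isoelectric point,
  P(helix), steric hindrance, P(sheet), flexibility — the basic
  physicochemical scales, chosen to be weakly inter-correlated.
* **Set 2** (2): in vivo decay time and cost for synthesis — metabolic
  descriptors, larger values for more expensive amino acids.
* **Set 3** (16): precomputed composites of Set 1 (ratios, products, one
  sum), e.g. `Volume/P(helix)`; derived amino-acid-wise by
  `derive_composites()` from the **raw** (uncentered, unscaled) Set 1 values.
  Raw scales are used throughout because the fits are affine-invariant in the
  descriptor: $r$, RMSE and $p$ do not change under $d \mapsto a d + b$
  ($a>0$), and $a<0$ only flips the reported trend.
* **Set 4** (4): discrete side-chain composition counts (O, N, S atoms, and
  H-bond donors + acceptors). Counted on the side chain only, His in its
  neutral form; each O/N/S site contributes one acceptor plus one donor per
  polar hydrogen.

The numeric values shipped are standard published scales (Zamyatnin volumes,
Fauchère–Pliska hydrophobicity, Chou–Fasman propensities, Charton steric
parameter, Bhaskaran–Ponnuswamy flexibility, N-end-rule half-lives,
Akashi–Gojobori biosynthetic costs, CRC-style solubilities); every table
carries a provenance string, and `aa_catalog(file=)` accepts a complete
tab-delimited replacement so any exact scale can be substituted and results
remain auditable. Ratio composites are computed directly — none of the shipped
denominators is zero — and a custom scale that would produce a zero
denominator is rejected rather than silently yielding infinities.

## Per-site screening

For each site with response vector $y$ (20 points), and each descriptor $d$
of the selected sets in catalog order:

1. Ordinary least squares of $y$ on $d$ (order 1), optionally also on
   $(d, d^2)$ (order 2). Reported per fit: coefficients, $r$ (Pearson
   correlation of response with fitted values), RMSE
   ($\sqrt{\tfrac1n\sum e_i^2}$), and the overall regression F-test p-value —
   for order 1 identical to the two-sided correlation $t$ test.
2. **Bonferroni**: $p_{adj} = \min(1, m\,p_{raw})$ with $m$ = number of
   descriptors screened *at this site* (doubled when quadratic models are
   also screened, since each descriptor is then tested twice). The correction
   is per site; no cross-site correction is applied.
3. Fits with $p_{adj} \le \alpha$ (default $\alpha = 0.05$) that also pass
   the optional $r_{\min}$/RMSE$_{\max}$ limits are retained.
4. **Best fit**: the scan seeds with the first retained fit and a later fit
   replaces the incumbent only if it lowers the RMSE *and*
   $F = (\mathrm{RMSE}_{inc}/\mathrm{RMSE}_{chal})^2$ exceeds the upper
   $f_\alpha$ critical value of the F distribution with
   $(n-q_{inc},\, n-q_{chal})$ degrees of freedom ($q$ = number of fitted
   coefficients, default $f_\alpha = 0.05$). Ties keep the incumbent, so the
   Set 1 → 4 scan order means composite or discrete descriptors win only when
   they are *statistically* better than a simple scale. Within one
   descriptor, the quadratic model displaces the nested linear one only by
   the standard extra-sum-of-squares F test at $f_\alpha$.

A quadratic fit's trend is classified by the sign of the correlation between
its fitted curve and the descriptor (such fits are curved yet
near-monotone in practice). Sites whose response takes fewer than three
distinct values (e.g. fully conserved sites) are degenerate for regression,
are never fitted, and fall through to the tolerance-based classes. A constant
response returns a degenerate model with $p_{raw}=1$.

Sites are then classified: **explained** (has a best fit), or unexplained
with **very low tolerance** ($k^\* < 4$, conserved, active-site-like), **very
high tolerance** ($k^\* > 16$, nearly unconstrained), or **intermediate
tolerance**. The thresholds 4 and 16 are configurable defaults. Summary
percentages are over all sites with data; the per-descriptor "share of
explained" column is labelled as such.

The screen is fully deterministic given the table, catalog and
configuration.

## What the synthetic generators emulate — and what they do not

The generators produce the three archetypes the screen must distinguish:

* `gen_planted_table()`: response $= \beta d + \varepsilon$,
  $\varepsilon \sim N(0, \sigma)$ — a site genuinely shaped by one
  descriptor. Gaussian noise on the response scale matches the least-squares
  assumptions, so power and error rates are interpretable.
* `gen_null_table()`: i.i.d. Gaussian responses — no descriptor dependence.
* `gen_conserved_table()`: one-hot sites, $k^\* = 1$.
* `gen_alignment()`: multinomial sampling of columns from known profiles,
  optional gap fraction, query first.

Responses are re-encoded into either metric by affine maps (negate-and-shift
for `ddg`, min-shift for `preference`), which leaves $r$, $p$ and RMSE
untouched. All generators take explicit seeds.

The benchmark mixture used in the validation suite is 500 sites — 60% planted
round-robin across the Set 1 descriptors with random slope signs and noise
$\sigma = 0.1\,|\beta|\,\mathrm{sd}(d)$, 30% null, 10% conserved. At that
signal-to-noise the screen recovers ≥95% of planted sites with the correct
descriptor and trend and flags ≥95% of conserved sites as low-tolerance;
on 1,000 null sites the fraction with any retained Set 1 fit stays within the
binomial envelope of $\alpha = 0.05$ (these sizes keep the whole validation
suite under a minute on one core while leaving the binomial bounds tight
enough to be meaningful).

What the generators deliberately do **not** model: selection dynamics,
library-construction bias, sequencing error, codon structure, phylogenetic
correlation between alignment rows, intragenic epistasis and coevolution.
Real alignment columns are not independent draws and real DMS scores carry
structured noise, so passing these benchmarks demonstrates the statistical
machinery is correct — not that every biological dataset will be as clean.
On real data the unexplained-intermediate class absorbs sites shaped by
multiple interacting properties, coevolutionary constraints, or
transcription/translation-level effects the per-site model cannot see.

## Numerical and formatting choices

* Regression via `stats::lm`; p-values from the F statistic
  (`stats::pf`), replacement decisions from the F quantile/CDF.
* RMSE uses the population form ($1/n$), matching its role as a plain
  back-prediction error; the replacement test's degrees of freedom carry the
  coefficient counts.
* `k*` terms with $f_i = 0$ contribute zero to the entropy.
* The tab-delimited table dialect is 22–24 fields (wild type, residue
  number, 20 preferences, optional $k^\*$, optional extra column); a header
  row fixes the amino-acid column order, otherwise it is alphabetical by
  one-letter code. Tables written by the package round-trip through the
  parser.
* `bfactor_annotate()` rewrites only columns 61–66 of `ATOM`/`HETATM`
  records and preserves everything else byte for byte, so rewritten files
  remain valid for any downstream viewer.
* PyMOL selections are emitted as `select <name>, chain <C> and resi
  n1+n2+...`, VMD selections as `chain <C> and resid n1 n2 ...`; an empty
  filter yields the comment `# empty selection`.

## Known limitations

Single-descriptor models only — no multivariate or epistatic fits, no
coevolution analysis, no alignment construction, no codon-level data. With 20
points per site the quadratic option costs power (the Bonferroni family
doubles) and should be used when an optimum-seeking shape is plausible.
Descriptor scales are inevitably inter-correlated; the replacement F test
arbitrates, but on noisy data the reported best descriptor for a site should
be read as "a good simple explanation", not a unique cause.
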