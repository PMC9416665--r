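---
title: "memprop: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memprop: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprop)
```

## The problem

Intrinsically disordered regions (IDRs) often function by associating with
acidic membranes, and the association is residue-specific: a few basic
stretches do most of the work while acidic stretches stay off the bilayer.
Direct measurement — long MD simulations against a lipid bilayer, or NMR
titrations with liposomes — is slow and expensive. `memprop` predicts a
per-residue association propensity from the amino-acid sequence alone.

## The partition-function score

Each residue is assigned a charge class: positive (K, R), negative (D, E),
neutral (everything else, including histidine — the three-class scheme
treats only K/R/D/E as charged). The statistical weight of residue $n$ is a
product over *all* sites $i$ of the sequence:

$$w_n = \prod_{i=1}^{N} q_{i;|i-n|}, \qquad
q_{i;d} = 1 + \frac{q_{i;0} - 1}{1 + a_i d + b_i d^2}$$

Each site contributes a Boltzmann-like factor whose amplitude $q_{i;0}$
depends on its class and which decays toward 1 (no effect) with sequence
distance $d = |i - n|$. The product includes $i = n$ itself (the $d = 0$
factor is the bare class amplitude). The reported propensity is
$P_n = c\, w_n / w_{\max}$ with $w_{\max} = \max_n w_n$, so profiles are
relative by construction; the per-protein scale $c$ (default 1) has meaning
only against an observed profile.

Assumptions worth keeping in mind:

* additivity in log space — residues contribute independent multiplicative
  factors; cooperative effects (helix formation, lipid clustering around a
  basic patch) are absorbed into the trained amplitudes on average;
* charge is the only sequence feature — hydrophobicity and aromaticity are
  not scored, which is why a separate amplitude set exists for
  amphipathic-helix-containing IDRs;
* no lipid-composition dependence — the amplitudes average over the acidic
  membranes present in the training data.

### Parameters

| parameter | meaning | units | value |
|---|---|---|---|
| $q_+$, $q_-$, $q_0$ | class amplitudes at $d=0$ | — | trained (below) |
| $a_\pm$, $b_\pm$ | attenuation, charged classes | res$^{-1}$, res$^{-2}$ | 0.0982, 0.00305 |
| $a_0$ ($b_0 = 0$) | attenuation, neutral class | res$^{-1}$ | 0.521 |

The attenuation constants are inherited from the nanoparticle-binding
predecessor of this model and are frozen everywhere, including during
fitting; only the three amplitudes are trained. The two shipped sets are
`preset_params("disordered")` — $q_+ = 2.43$, $q_- = 0.26$, $q_0 = 0.59$,
trained on fully disordered IDRs — and `preset_params("helix")` —
$q_+ = 2.29$, $q_- = 0.64$, $q_0 = 1.17$, trained where amphipathic
helices dominate ($q_0 > 1$ reflecting neutral residues buried in the
bilayer). The set is user-selected (`--mode`); nothing auto-detects helix
content, and `disordered` is the default for plain prediction.

### Terminal charges

The free $\alpha$-amino and carboxylate groups carry charges of their own.
The convention here (the design was genuinely open): `termini = "free"`
adds a positive pseudo-site co-located with residue 1 and a negative
pseudo-site co-located with residue $N$; their factors multiply into $w_n$
with distances $|1-n|$ and $|N-n|$, and the terminal residues keep their
own classes. This mirrors the additive treatment in the toy model (where
the terminus charge adds to the residue charge) and degrades gracefully:
`"capped"` simply drops both pseudo-sites, appropriate for an IDR excised
from mid-chain. An alternative reading — overriding the terminal residue's
class — is not implemented; the switch covers the practical cases.

### Numerical choices

* $w_n$ is computed as a sum of log factors, then exponentiated: a
  2000-residue basic sequence overflows a double in direct product form.
  All factors are bounded away from zero for valid parameters
  ($q_{i;d}$ lies between $\min(1, q_{i;0})$ and $\max(1, q_{i;0})$), so
  the logs are finite. Equivalence with the naive product is asserted to
  1e-10 relative over random sequences.
* Profile normalization takes the first index at ties (`which.max`); exact
  ties occur only for symmetric sequences, where either choice is valid.
* Propensity indices are 1-based over the supplied sequence; an integer
  `offset` maps them to author/UniProt numbering in all outputs.

## The z-tip map

Training targets can come either from raw 3.5-Å heavy-atom contact
fractions or from the mean height $z_\mathrm{tip}$ of each side chain's
tip atom above the phosphate plane. The map

$$C(z) = \frac{1}{1 + e^{(z - z_0)/L(z)}}, \qquad
L(z) = L_1 - \frac{L_1 - L_0}{1 + e^{(z - L_m)/L_w}}$$

with $z_0 = 6.9$ Å, $L_1 = 3.2$ Å, $L_0 = 1.2$ Å, $L_m = 5.0$ Å,
$L_w = 0.5$ Å converts heights into contact probabilities with a softness
that itself varies with height (contacts blur more for residues hovering
above the plane). Exponents are clamped to $\pm 700$ before
exponentiation — beyond that the probability is 0/1 to machine precision
and `exp` would overflow. Which atom is "the tip atom" is defined
upstream; `memprop` only consumes precomputed heights (`ztip2c`).
Numerically, $C$ is strictly decreasing over any physically meaningful
range even though $L$ varies with $z$ (verified on a dense grid in the
tests).

## The toy baseline

The moving-average charge over a seven-residue window (charges +1/−1/0,
free termini adding +1/−1 at the chain ends) is kept as a deliberately
naive comparator, with an OLS regression (`linear_fit`) against observed
profiles. Edge windows are truncated and the mean is taken over the
positions actually in range, so every residue has a value interpretable as
a mean charge in $[-1, 1]$; dividing by the nominal window width instead
would shrink edge values artificially. With a constant observed profile
the regression explains nothing and $R^2$ is reported as 0; a constant
predictor is an error. The comparator accepts either a single pooled fit
or per-protein fits — pooling was left open, so both modes are reachable.

## Fitting the amplitudes

`fit_amplitudes` minimizes the pooled per-residue squared error across all
proteins. Granularity was open; pooling matches how accuracy is reported
(per-protein RMSEs plus one global $R_0^2$). Two structural choices:

* **Profiled scales.** For fixed amplitudes, each protein's scale has the
  closed-form least-squares solution $c = \sum C_n r_n / \sum r_n^2$
  (clipped at 0), with $r_n = w_n/w_{\max}$. Solving $c$ inside the
  objective removes one parameter per protein from the search; the tests
  verify against a brute-force grid that the profiled objective equals the
  joint optimum.
* **Log-space box constraints.** Optimization runs L-BFGS-B on
  $\log q$ with bounds $q \in [0.01, 20]$, from 10 seeded starts (the
  user's `init` plus 9 log-uniform draws); the best converged run wins and
  non-convergence is flagged, never silent. The objective surface is
  smooth and the multi-start makes the result deterministic given
  `--seed`.

Goodness of fit is reported as per-protein RMSE and a pooled
$R_0^2 = 1 - \sum(\mathrm{pred}-\mathrm{obs})^2 / SS_\mathrm{tot}$. The
$SS_\mathrm{tot}$ convention was ambiguous in the source material; the
default takes it about the observed mean (the standard coefficient of
determination about the parity line), with `center = "zero"` available for
the raw-sum-of-squares reading.

Amplitudes whose charge class never occurs in the training sequences
(counting terminal pseudo-sites) leave flat directions in the objective;
the fit warns and flags them as non-identifiable rather than reporting an
arbitrary bound value as meaningful.

`leave_one_out` refits with each *group* of proteins held out —
sequence-similar proteins share a group label and leave together, so a
fold never trains on a near-duplicate of its test protein — and
summarizes each amplitude as mean ± sd across folds.

## The synthetic world

The generator exists so that every module is testable with no downloads:
`random_idr_sequence` draws sequences of controlled charge composition
(defaults 15% positive, 15% negative — typical of the charged,
membrane-binding IDRs the method targets) and `synthetic_contact_profile`
produces observations from the model itself,
$C_n = \mathrm{clip}(c\,w_n/w_{\max} + \varepsilon_n,\, 0,\, 1)$ with
independent Gaussian noise (default $\sigma = 0.02$, the scatter level
used in the recovery criteria; per-protein scales drawn in $[0.4, 0.9]$).
One integer seed drives sequence and noise substreams.

What a green recovery test establishes: the optimizer correctly inverts
the model under realistic noise, and the identifiability structure is as
described. What it does **not** establish: that the model describes real
membranes. Real MD or NMR profiles contain structure the generator omits —
autocorrelated errors, helix-induced cooperativity, lipid-composition
effects, systematic model misfit. The published training profiles are not
publicly deposited, so the headline accuracy numbers (RMSEs of
0.01–0.04 for disordered IDRs, pooled $R_0^2 \approx 0.9$) are context,
not reproduced results; synthetic recovery is the package's stand-in.

## Known limitations

* Three charge classes only; no hydrophobicity, aromaticity, or
  separation of R from K. Helix-containing IDRs are served by a separate,
  compromise amplitude set.
* No lipid-composition dependence and no modeling of lipid redistribution
  around bound residues.
* The per-protein scale $c$ is not predictable from sequence; absolute
  contact probabilities require an observed profile to calibrate against.
* Terminal pseudo-sites are a modeling convention (see above); predictions
  within two or three residues of a free terminus carry that uncertainty.
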