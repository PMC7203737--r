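---
title: "First-order Markov mixture models for monomeric and dimeric TF motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order Markov mixture models for monomeric and dimeric TF motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A transcription factor's binding motif is modelled here as an
**adjacent dinucleotide matrix (ADM)**: an inhomogeneous first-order Markov
chain over the DNA alphabet. A motif of length $\ell$ has an initial base
distribution at position 1 and, at every position $h = 2,\dots,\ell$, a
$4\times4$ matrix of conditionals $\theta_{ab,h} = P(X_h = b \mid X_{h-1} =
a)$, so the probability of a site $a_1\cdots a_\ell$ is
$\prod_h \theta_{a_{h-1}a_h,h}$. Unlike the classic position-specific
probability matrix (the order-zero special case, in which conditionals do
not depend on the predecessor), an ADM can express dependencies between
adjacent positions — base stacking, amino acids contacting two bases, or a
factor's alternative binding modes.

Transcription factors frequently bind as **dimers**. A dimeric motif is
composed of two monomer ADMs in a relative *orientation* (`HT`, `HH`, `TT`,
`TH`, realized by reverse-complementing one or both monomers) at a signed
*spacing* $d$ — the distance from the right end of the first oriented
monomer to the left end of the second, with $d<0$ meaning an overlap of
$|d|$ bases. When the gap is at least the independence threshold $\delta$
(default 4), the dimer is modelled as the *product* of its monomers with
background-filled gap columns. Below $\delta$ the two binding surfaces may
interfere, so the $|d|+2$ middle columns (gap or overlap plus one column of
each flank) are replaced by a freely learned **bridging component**
$\psi$. The derived **deviation** $\kappa = \psi - \text{expected}$ makes
the co-operative effect of dimerization explicit: it is the zero matrix
exactly when the dimer behaves as two independent monomers.

The full model is a probabilistic mixture $\eta = (\theta, \psi, \lambda)$:
a background model $\theta_0$, monomer ADMs $\theta_1..\theta_p$, all
dimers of the configured monomer pairs over a spacing grid, and mixing
weights $\lambda$ with $\lambda_0 = 1 - \sum_k \lambda_k$. Per monomer
pair, the weights over orientations $\times$ spacings form the
**co-operative binding (COB) table**, reported in integer multiples of
0.001.

# Learning

`run_em()` fits all components simultaneously by a ZOOPS
(zero-or-one-occurrence-per-sequence) EM: each read either contains exactly
one motif instance — any component, any admissible start, either strand,
with the remaining positions explained by background — or is background
throughout. Monomers are initialized from user-given IUPAC seeds (allowed
bases share `match_weight = 0.8`), bridging components from the expected
slices ($\kappa = 0$), and the weights with $\lambda_0 = 0.5$ and the rest
uniform; the paper-defaults `maxiter = 150`, `epsilon = 0.001`, `delta =
4`, `rho = 3` and spacing interval $[-\lfloor\min(\ell_1,\ell_2)/2\rfloor,
10]$ are the `em_config()` defaults. Convergence is declared when the
**weighted maximum norm** between consecutive models —
$\max_k \max(|\Delta\lambda_k|, \min(\lambda_k,\lambda_k')\cdot
\max|\Delta M_k|)$ over components, our concrete reading of that norm —
falls below `epsilon`.

Three pruning heuristics temper the pure EM:

* **Weak-dimer removal.** Dimers whose weight drops below `1e-4` (checked
  from iteration 3) are removed permanently and reported as pruned COB
  cells. The threshold and starting iteration quantify a "very small"
  weight; they are deliberately conservative.
* **Isolated-occurrence monomer learning.** Monomer matrices accumulate
  counts only from monomeric placements and from half-sites of dimers with
  $d \ge \delta$; half-sites of closer dimers are distorted by the partner
  and feed only the bridging components. With no dimer pairs configured
  (monomeric mode), monomers learn from all their placements.
* **Hamming restriction.** Matrix counts are restricted to placements
  within Hamming radius `rho` of the component's current consensus (for
  dimers, per half-site against the oriented monomer consensus). The
  restriction applies to the *learning of the matrices*; mixing weights
  are estimated from the unrestricted posteriors. We verified the
  alternative — filtering the weights as well — and it systematically
  deflates $\lambda$ of any motif whose expected Hamming distance from its
  consensus approaches `rho` (degenerate motifs at small radii), which
  contradicts the published recovery behaviour across radii; hence this
  design.

Numerical choices: all placement scoring is done in log space with a
per-read log-sum-exp; every re-estimation adds a pseudocount (default
0.01) per count cell; consensus ties break towards the alphabetically
smaller base; reverse-complementing an ADM whose predecessor state has
zero marginal mass substitutes a uniform row (the state is unreachable, so
no sequence probability changes, but a warning is raised); reads may
contain `N` — placements overlapping an `N` are inadmissible and fully
ambiguous reads count as background-only.

The exported `e_step()` / `hamming_filter()` / `m_step()` operations
mirror these stages for inspection; `m_step()`'s `lambda_table` argument
is how the driver separates weight estimation from matrix estimation.

# The simulator

`generate_reads()` draws reads from the same generative story the learner
assumes: component by $\lambda$, an instance sampled from the composed
dimeric ADM (bridging columns included), a fair-coin strand, a uniform
admissible start, background elsewhere, with the ground truth logged per
read. `build_sanity_model()` builds the homodimer mixture used throughout
the tests — uniform background $\lambda_0 = 0.70$ and homodimers HT 4
(0.061), HH 4 (0.055), HH 2 (0.068), TT 2 (0.034), HH 5 (0.082),
rescalable to total signal fractions 0.03/0.30/0.90 — around a HOXB13-like
monomer.

Because the real HOXB13 matrix is not shipped, `hoxb13_standin_adm()` is a
**synthetic stand-in** built from the seed `CYMRTAAAA`: invariant
positions at 0.94, and the two-fold degenerate Y/M/R positions with a
0.60/0.26 preference ordering plus explicit dinucleotide couplings (a C at
the Y position favours A at the M position, and so on). The preference
ordering, rather than an even IUPAC split, matches the shape of matrices
actually learned from HT-SELEX; an evenly split degenerate motif has an
expected Hamming distance from its consensus of about two per half-site,
which no small-radius seed-driven method can tolerate. `read_adm()` loads
a real matrix where one is available.

What the simulator does **not** emulate: SELEX enrichment cycles and PCR
bias, sequencing error and quality scores, multiple occurrences per read,
and flanking-primer composition (constant flanks are available in
`em_config(flanks=)` but are excluded from background re-estimation by a
clamped subtraction, an approximation). Passing the recovery tests
therefore shows the estimator is correct under its own generative
assumptions, not that real HT-SELEX data satisfies those assumptions.

# Model fit by k-mer spectra

`count_kmers()` / `score_kmers()` / `r_squared()` quantify fit as the
squared Pearson correlation between canonical k-mer occurrence counts
(both strands collapsed) and the mixture's k-mer scores. A k-mer's score
sums, over components and over every full-containment alignment of the
component against the k-mer window on both strands,
$\lambda_k P(\text{window}) / N_k$ — overhanging component positions enter
through the component's marginals, positions outside a short component
through the background — plus $\lambda_0 P_{bg}(w)$. Raw-scale correlation
is the default; `log_scale = TRUE` and a `min_count` filter are provided
because low-count k-mers dominate neither convention consistently.

# Design choices on open points

* **Background order.** The background defaults to order zero (uniform,
  or estimated from non-motif positions each M-step); an order-one
  background is accepted but kept fixed during learning.
* **Homodimer orientations.** Homodimers use `{HT, HH, TT}`; `TH`
  duplicates `HT` by strand symmetry. `em_config(orientations_homo=)`
  overrides this.
* **Overlapping dimers.** Inside an overlap two order-one chains disagree
  on conditioning, so the expected model uses the renormalized elementwise
  product of the monomers' position marginals (order zero within the
  overlap), after which the second monomer continues with its own
  conditionals.
* **Distance across structure changes.** Pruning changes the component
  set, so `model_distance(strict = FALSE)` aligns two models on the union
  of components, counting a missing component at weight zero; this is also
  how learned models are compared to generating ones.
* **Submodel selection.** The 85% rule adds components by decreasing
  weight until the selected weights cover the threshold fraction of the
  non-background signal; ties prefer monomers, then lexicographic order,
  and selected weights keep their original values.

# Problem sizes used by the tests

The test-suite relearns use 20000 reads of length 40 (the radius sweeps
10000, the co-operativity recovery 50000, the k-mer self-consistency
100000 for counting and 20000 per decoy replicate); these sizes keep every
recovery bound comfortably inside its statistical noise floor while the
whole suite stays conveniently re-runnable. Two identifiability facts
shape the co-operativity fixture: an HH homodimer is strand-symmetric up
to $\psi$, so ZOOPS strand posteriors smear an asymmetric injected
deviation (the fixture uses HT); and deviation cells conditioned on
rare predecessor bases are estimated from few effective counts, so the
fixture's monomer has balanced boundary columns.

# Known limitations

* Markov order is fixed at one; no higher-order or non-adjacent
  dependency structure.
* Dimers only — no trimers or higher multimers.
* The Hamming restriction presumes a sensible seed; a seed far from every
  true motif can leave a component uninformed (the EM then drives its
  weight toward zero rather than failing).
* Logo rendering is limited to structured JSON export
  (`export_logo_data()`); no graphics are produced for dependency logos.
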