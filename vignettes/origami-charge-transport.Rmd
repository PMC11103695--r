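---
title: "Decoherent charge transport in DNA origami models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoherent charge transport in DNA origami models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single DNA duplexes conduct charge through the stacked pi systems of their
bases. DNA origami bundles several duplexes into a rigid object by routing
strands between helices at crossovers (Holliday junctions). Whether an
origami conducts like its component duplexes — and how the answer depends on
where the electrodes sit — is the question this package operationalizes: it
takes an annotated one-electron Hamiltonian of a duplex or a two-helix,
one-crossover origami and computes frontier-orbital structure, per-atom
density of states, and two-terminal conductance under every terminal-base
electrode placement.

## The transport model

The input is an `electronic_system`: a Fock matrix $H_0$ and overlap matrix
$S_0$ in a non-orthogonal basis (eV throughout), plus an atom table mapping
orbitals to atoms, bases, strands, helices and region tags, and the number
of doubly occupied orbitals. Three exact basis transformations and one open
-system calculation follow.

**Löwdin orthogonalization.** $H_{\mathrm{orth}} = S_0^{-1/2} H_0
S_0^{-1/2}$ preserves the generalized spectrum of $(H_0, S_0)$ and yields an
orthogonal basis in which squared eigenvector components are well-defined
(Löwdin) populations. $S_0^{-1/2}$ is computed by eigendecomposition of
$S_0$ with an explicit eigenvalue floor (default $10^{-8}$): a near-singular
overlap is an input defect and is reported, never silently regularized.

**Atom-block diagonalization.** $H_{\mathrm{orth}}$ is partitioned into
per-atom blocks and each diagonal block is rotated to its own eigenbasis.
Diagonal elements then hold atomic molecular-orbital energies; off-diagonal
blocks hold inter-atomic hoppings. The transform is block-diagonal unitary,
so the global spectrum is untouched (this is asserted to $10^{-8}$ eV in the
tests). Within an atom, eigenvector columns are ordered by ascending
eigenvalue, each column's largest-magnitude component is made positive, and
degenerate levels (below $10^{-10}$ eV) keep the original orbital order —
three conventions that make hoppings bit-reproducible.

**Büttiker-probe transport.** The retarded Green's function is
$G^r(E) = [(E + i\eta) I - H - \Sigma_L - \Sigma_R - \Sigma_B]^{-1}$.
Electrodes are represented by broadening only: $\Sigma_{L(R)}$ carries
$-i\,\Gamma_{L(R)}/2$ on every orbital of the contact atoms; every remaining
atom gets its own decoherence probe with $-i\,\Gamma_B/2$ on its orbitals.
Pairwise transmissions are $T_{ij} = \mathrm{Tr}(\Gamma_i G^r \Gamma_j
G^a)$; with diagonal couplings this reduces to a weighted sum of
$|G^r_{\alpha\beta}|^2$, which is how it is evaluated (the trace form is the
test oracle). Probe potentials float to carry zero net current, obtained by
solving $W \mu = b$ with $W_{ij} = (1 - R_{ii})\delta_{ij} - T_{ij}(1 -
\delta_{ij})$ and $R_{ii} = 1 - \sum_{j \ne i} T_{ij}$ (flux conservation —
the only definition under which $W$ is the standard Büttiker matrix and
current is conserved, which the suite checks to $10^{-9}$). The effective
transmission is
$T_{\mathrm{eff}} = T_{LR} + \sum_{ij} T_{Li} (W^{-1})_{ij} T_{jR}$;
$W$ is an M-matrix, so the decoherent correction is nonnegative and
$T_{\mathrm{eff}} \ge T_{LR}$ always. Zero-bias conductance is $G = G_0
T_{\mathrm{eff}}(E_F)$ with $G_0 = 2e^2/h$; the Fermi energy defaults to the
HOMO, and curves from different systems are compared on the HOMO-aligned
axis.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `gamma_contact` ($\Gamma_{L,R}$) | 0.600 | eV | electrode broadening on each terminal-base atom's orbitals |
| `gamma_probe` ($\Gamma_B$) | 0.010 | eV | decoherence-probe broadening on every non-contact atom |
| `temperature` | 300 | K | recorded for provenance; the zero-bias linearization does not use it |
| `eta` | $10^{-6}$ | eV | numerical floor in $G^r$; physical broadening comes from $\Sigma$ |
| Fermi offsets | 0–0.3 | eV | conductance evaluated at HOMO $+$ offset |

$\Gamma_{L,R} = 600$ meV and $\Gamma_B = 10$ meV are the conventional
coupling strengths of this framework; because the self-energy convention is
$\Sigma = -i\Gamma/2$, these numbers are directly the Breit–Wigner widths
(the single-site transmission reproduces
$\Gamma_L\Gamma_R / [(E-\varepsilon)^2 + ((\Gamma_L+\Gamma_R)/2)^2]$ to
$10^{-10}$ over a 400-point grid). The probe granularity is one probe per
atom, coupling all of that atom's orbitals; per-orbital probes were
considered and rejected as a different physical model. With $\Gamma_B = 0$
all probes decouple, their potentials are reported at zero, and
$T_{\mathrm{eff}} \to T_{LR}$ — the suite checks this limit is approached
monotonically over $\Gamma_B \in \{10^{-2}, 10^{-4}, 10^{-6}\}$ eV.

## The synthetic generator

Reference Fock/overlap matrices from quantum chemistry are rarely shippable,
so the package generates annotated tight-binding stand-ins with the same
container, annotations and qualitative spectral structure:

* **Sites.** One pi site per base on every strand; one backbone site per
  internal phosphodiester linkage ($L-1$ per strand: 14 sites for an 8-bp
  duplex, 28 for a four-strand origami — the phosphate counts behind net
  charges of $-14$ and $-28$). Terminal bases carry no phosphate.
* **Site energies** (eV): $\varepsilon_G = -7.8$, $\varepsilon_A = -8.1$,
  $\varepsilon_C = -8.3$, $\varepsilon_T = -8.4$ — chosen only to satisfy
  the orderings guanine $>$ adenine $>$ cytosine $>$ thymine and
  $\varepsilon_G - \varepsilon_C = 0.5$ eV (the G/C intra-band offset);
  absolute values are arbitrary. Backbone sites sit at $\varepsilon_G - 2$
  eV, far below the HOMO, which is what starves the crossover of states.
* **Couplings** (eV): stacking $t_{\mathrm{stack}} = -0.10$, pairing
  $t_{\mathrm{pair}} = -0.05$, base–backbone $t_{bb} = -0.08$,
  backbone–backbone $t_{\mathrm{chain}} = -0.12$, inter-helix $t_x = -0.06$
  (C2 only). These keep the model in the weak-coupling regime where
  base-character labels are crisp. A uniform overlap $s = 0.05$ decorates
  every coupled orbital pair.
* **Occupations.** Each base site carries one doubly occupied pi orbital
  plus one vacant orbital 4 eV above it; each backbone site one occupied
  orbital. `n_occupied` is therefore the number of sites — stored in the
  bundle, never guessed. A single-orbital-per-base granularity was
  considered and rejected: with every model orbital occupied there is no
  LUMO, no gap, and the container's occupation invariant
  ($0 < n_{\mathrm{occ}} < n_{\mathrm{orb}}$) cannot hold. A "rich"
  three-orbitals-per-base setting exercises multi-orbital atom blocks.
* **Topology.** A duplex is two antiparallel complementary strands (the
  builder derives the partner strand). The origami is two such duplexes
  whose crossing strands exchange backbone connectivity at one internal
  position: the intra-strand backbone link between sites $x$ and $x+1$ is
  severed on both crossing strands and replaced by the two inter-helix
  links, and the four flanking backbone atoms are tagged
  `region = "crossover"`. C1 has no base–base contact between helices; C2
  adds $t_x$ between one terminal base of each helix, modeling the
  conformer in which one helix leans toward the other. No quantitative
  correspondence of $t_x$ to any real conformer is claimed.

**What the generator does not emulate.** Real DFT systems have hundreds of
orbitals per base with inhomogeneous couplings, solvent screening, and
MD-conformer disorder; the generator's systems are small, ordered and
noiseless unless jitter is requested. Passing tests therefore demonstrate
the correctness of the transformations and transport algebra and the
qualitative transferability of the barrier/localization phenomenology — not
quantitative agreement with any measured or computed DNA conductance.

## Overlap renormalization: a deliberate subtlety

With site energies near $-8$ eV, Löwdin orthogonalization renormalizes the
effective coupling on a bond to roughly $t - s\bar\varepsilon \approx t +
0.4$ eV at the default $s = 0.05$. Three perturbative expectations that hold
exactly in the $s = 0$ model are visibly stretched at the default overlap:
the poly(G)·poly(C) HOMO weight on the G strand is 0.81 rather than
$> 0.9$; the top guanine-derived DOS peak sits 0.63 eV (not 0.50 eV) above
the cytosine-derived one; and the cross-helix conductance is monotone in the
*effective* coupling $|t_x - sE|$, not in $t_x$ itself. The tests assert the
clean perturbative statements at $s = 0$ and pin the default-overlap
behavior to oracle-computed values, and the defaults are left untouched:
overlap-driven renormalization is a real feature of non-orthogonal bases,
not a defect of the generator.

## Numerical choices

* Energy unit is eV end to end; bundles record it.
* The TSV bundle stores matrices as their nonzero lower triangle printed
  with `%.17g`, which round-trips IEEE doubles bit-exactly; the HDF5 layout
  stores the packed lower triangle as 64-bit floats.
* Degenerate and decoupled probes: a probe whose $W$ row is numerically
  zero carries no flux and is reported at potential 0; a $W$ block with
  condition number above $10^{12}$ (an atom with no path to the contacts)
  raises an error at single energies and flags the energy in spectrum
  drivers rather than regularizing.
* Noiseless origami have exactly degenerate helices, so frontier orbitals
  delocalize 50/50 by symmetry. Localization comparisons between C1 and C2
  are therefore run on jitter-perturbed copies (0.05 eV site-energy noise,
  same seed for both conformers), which plays the role of the
  conformational asymmetry always present in real structures. Conductance
  comparisons do not need this and run on noiseless defaults.
* Randomness: every stochastic operation takes an explicit seed and
  restores the global RNG state; identical parameters and seed give
  bit-identical systems and output tables.
* Problem sizes: the shipped analyses use 8-bp systems (46 orbitals per
  duplex, 92 per origami), 120–400-point transmission grids, 200-replicate
  jitter ensembles, and 50-system random corpora for the spectrum oracle —
  sizes chosen so the complete analysis reruns from scratch in about a
  minute on a laptop core while leaving every assertion tight.

## Known limitations

* Zero-bias linear response only; no finite-bias I–V, no inelastic
  (phonon) self-energies, no hopping/polaron regime.
* Electrodes are broadening matrices; no atomistic gold or linker
  chemistry, so absolute conductances inherit the $\Gamma$ convention.
* The `both` scheme ties the two helices' contacts to a common electrode
  potential; independent four-terminal operation is not modeled, and
  `both` $\ge$ max(single-helix) is *not* asserted — interference can
  violate it.
* DOS uses the transport Green's function (contacts + probes) so DOS and
  transmission describe one open system; a bare-broadening mode exists for
  closed-system spectral checks.
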