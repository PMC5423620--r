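---
title: "Screening and characterizing viral histone H4 joining sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and characterizing viral histone H4 joining sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h4map)
library(dplyr)
```

## The biological problem

Some parasitoid wasps deliver a symbiotic bracovirus into their caterpillar
host at oviposition. Among the virus's products is a viral histone H4 with an
extended, lysine-rich N-terminal tail. The protein incorporates into host
nucleosomes and rewires host transcription epigenetically: immunity and
development genes are silenced, which favours the developing wasp larva.

Two genome-scale questions follow, and `h4map` implements the analysis chain
for both:

1. **Where does the viral H4 join the host genome?** Chromatin
   immunoprecipitation followed by sequencing (ChIP-Seq) yields, per
   condition, a table of candidate binding intervals ("peaks") with a
   significance value (E-value) and a read count. The screening logic is
   differential: peaks called in parasitized larvae (`P7`) are compared with
   nonparasitized controls (`NP5`), and peaks from larvae transiently
   expressing the full-length viral H4 (`vH4`) with larvae expressing a
   tail-truncated construct (`vH4T`). A *core target* is a gene that is the
   nearest gene of a treatment-specific peak in **both** screens.

2. **How much host gene regulation does the viral gene explain?** Four
   RNA-Seq FPKM tables (one per condition above) give two contrasts:
   parasitism (`P7/NP5`) and viral-gene expression (`vH4/vH4T`). The
   direction-concordant overlap of the two DEG lists, relative to the
   parasitism list, quantifies the viral gene's contribution.

The package consumes post-alignment products only — peak tables, FPKM
tables, a gene annotation, a scaffold/linkage-group table and the genome
FASTA. Read mapping, transcript assembly, FPKM computation and peak calling
are upstream and out of scope; the ChIP E-value in particular is treated
strictly as an input column, since different callers define it differently.

## The screening model

**Significance filter.** A peak survives at threshold $t$ iff its E-value
$\le t$ (inclusive; the printed convention "at E value of $10^{-8}$" names
the boundary, so the boundary is kept). The two screens use different
defaults, $10^{-8}$ for the parasitism screen and $10^{-13}$ for the viral
screen, reflecting their different mapping ratios; both are arguments, not
constants.

**Nearest-gene annotation.** The nearest gene minimizes the *edge-to-edge
gap* between peak and gene intervals. Midpoint or TSS distances were the
obvious alternatives; gap semantics were chosen because reported distances
(tens to hundreds of bp) are small relative to the 133–155 bp site widths,
which only makes sense edge-to-edge. The signed distance is positive when
the peak lies on the gene's strand-aware 5′ side, negative on the 3′ side,
zero on overlap; the locality label follows (`UP`, `DOWN`, `GB`). Two
boundary rules are fixed and tested rather than left to chance:

* *Equidistant ties* resolve to the lexicographically smallest gene id —
  arbitrary but deterministic, and flagged in tests by construction.
* *Exact adjacency* (gap 0 with no shared base) keeps its side label; `GB`
  requires at least 1 bp of true overlap.

A `ignore_strand` switch treats lower coordinates as upstream, matching
unstranded presentations of target tables; strand-aware is the default.

**Subtraction and intersection.** Control subtraction removes treatment
sites *by nearest-gene identity*, not by coordinate overlap: a control peak
anywhere near the same gene disqualifies it. Core targets are the genes
present in both screens' specific sets; when several sites in one screen
share a gene, the site with the smallest |signed distance| represents it
(tie on distance falls back to peak id).

## Expression model

Transcripts with a zero FPKM in any of the four conditions are removed
before fold changes are formed — fold changes are then always finite and the
filter bookkeeping (total, removed, retained) is part of the output. The
signed fold change is

$$\mathrm{FC}(t, c) = \begin{cases} t/c & t \ge c \\ -\,c/t & t < c \end{cases}$$

so $|\mathrm{FC}| \ge 1$ always and $-3$ reads as "3-fold down". Equal
values give $+1$: the sign at this measure-zero boundary is arbitrary and
documented. A DEG satisfies $|\mathrm{FC}| \ge 2$ — inclusive, because
printed DEG lists carry boundary values of exactly $-2.0$.

The overlap of two DEG lists is direction-concordant: genes up in both or
down in both; discordant genes belong to neither set. The contribution
percentage is reference-relative, $100 \cdot n_\mathrm{common} /
n_\mathrm{reference}$, reported half-up to one decimal *only* at the
reporting layer — internal values stay unrounded.

Functional-category composition of two DEG sets is compared by a Pearson
chi-square on the $2 \times k$ homogeneity table with $k - 1$ degrees of
freedom after dropping categories empty in both groups; eleven non-empty
categories hence give df = 10, matching the printed layout. The test is
delegated to `stats::chisq.test(correct = FALSE)`; the test suite verifies
it against the textbook $\sum (O - E)^2 / E$ independently.

## Sequence characterization

AT content is $(A + T)/(A + C + G + T)$, case-insensitive, with ambiguity
codes excluded from numerator and denominator alike.

The tandem-repeat finder reports **maximal runs of primitive units** of
length 2–5. A run is maximal when the periodicity fails just before its
start and just after its end; a run expressible under several unit lengths
(e.g. `AGAGAGAG` as `AG` or `AGAG`) is reported once under the shortest
(primitive) unit. `copies` counts complete units only — a trailing partial
unit sets a boolean flag instead of fractional copies, which keeps the
brute-force enumeration oracle exact. Homopolymers are excluded. Units are
classified by their lexicographically smallest rotation (`TG…` runs are
class `GT`), and reverse complements are **not** merged: `GT`/`AC` and
`CT`/`AG` are distinct classes, because the two strands' tallies are
reported separately; a property test asserts that reverse-complementing a
sequence maps each class to its complement class rather than collapsing
them.

Minimum copy numbers are configuration: 5 copies for dinucleotide units, 4
for trinucleotide, 3 for tetra- and pentanucleotide. No minimum is given in
the source material; these floors keep chance hits rare in 150-bp AT-rich
sequence (well under 1% of sites) while admitting the run lengths seen in
site alignments, and they are echoed in output headers so results are
interpretable.

## Position analysis

For each target gene a neighborhood of the focal gene plus three genes per
side is tiled into gene bodies and intergenic segments (including the two
outer bounding segments). Each peak contributes its full read count to the
region containing its midpoint — a peak straddling a boundary is not split,
which conserves total counts (the documented alternative,
overlap-proportional splitting, is not implemented). The three localities of
the focal gene are its gene body (`GB`) and the two intergenic segments
immediately adjacent to it (`UP` and `DOWN`, strand-aware) — not the whole
seven-gene span, so the domains match the realistic per-gene sizes (gene
body ≈ 1.5 kb, upstream ≈ 2.5 kb, downstream ≈ 3 kb). The main position is
the arg-max of the three counts with the fixed tie precedence UP > GB >
DOWN; profiles with no reads in the three regions are flagged rather than
called. Truncated neighborhoods at scaffold ends are kept and flagged.

Whether the "main" peak should be chosen by maximal read count or minimal
E-value is genuinely open; read count is the default here because it is what
the neighborhood profile aggregates, and the choice is confined to one
function argument.

The positional-effect test is a Pearson chi-square on the $3 \times 2$
locality-by-direction table (df = 2), excluding unregulated genes; empty
rows or columns are dropped with a warning and the df reduced. Under a null
simulation in which direction is independent of locality, the test's
empirical type-I error at $\alpha = 0.05$ is required (and verified over
10,000 simulated tables) to sit in $0.05 \pm 0.01$.

## Physical mapping

Linkage-group membership comes from the scaffold table only — never parsed
out of scaffold names, since both `ChrLG-5`-style and `SC_###`-style names
occur in real tables. Scaffolds without an assignment fall into the
uncharacterized bucket `LGUN`. Positions within a linkage group are
cumulative scaffold offsets in the scaffold table's order (no ordering is
inferred). The DEG overlay adds direction-labelled gene positions, flags
DEGs within a 1-kb window (edge-to-edge) of each target, counts DEGs on
linkage groups that carry no target at all, and never changes the target
bucketing.

## Coordinates and formats

All on-disk coordinates are 1-based inclusive (the dialect of the host
genome database and of printed target tables); internally every interval is
0-based half-open, so widths are `end - start` and adjacency is equality.
Readers convert on the way in, writers on the way out, and the round trip is
the identity (property-tested). BED export is written unchanged, since BED
is natively 0-based half-open. Tabular writers emit a commented header line
(`# col1<TAB>col2…`); readers accept that dialect or a plain header.
Sequences are always reported on the plus strand — strand enters the
analysis only through gene orientation.

## The synthetic-data generator

Real inputs for this kind of study are rarely deposited, so the package
ships a generator (`sim_config()`, `simulate_h4_dataset()`) whose defaults
*are* the study conditions wherever those are stated: 18,073 transcripts
with 5,128 planted zero-FPKM transcripts; 1,858 / 1,190 / 302 planted DEGs
split 877:981, 431:759 and 81:221 up:down; site footprints 133–155 bp at AT
fraction 0.602 against a 0.55 background; 40% of specific sites carrying a
planted tandem repeat with dinucleotide classes weighted GT > AC > CT > AG
plus a tail of 3–5-mers; E-values straddling the screening thresholds; and
realistic domain lengths (gene body 1.5 kb, upstream 2.5 kb, downstream
3.0 kb drawn with 15% CV). Where the study conditions are silent — genome
scale — the defaults are scaled down (20 scaffolds of 150 kb, 18 genes
each) so the full pipeline runs in seconds; tests use a smaller
configuration still (6 scaffolds of 80 kb, 12 genes each, 400 transcripts)
for the 100-seed recovery loops, and the acceptance script sizes one screen
to 480 specific sites when measuring sequence composition. Planted DEG and
zero counts are planted *exactly* (not binomially), so count bookkeeping is
sharp.

Noise is a single multiplicative log-normal factor per FPKM cell with
configurable CV (default 0.1, a plausible combined biological/technical
spread for this design; planted |FC| defaults to 4–64 so that recall at
threshold 2 stays above 95% under that noise, and to 1 exactly when the CV
is 0). Peak placement guarantees by construction that the planted gene is
the nearest gene, that |signed distance| stays below 1 kb, and that no two
planted footprints overlap (placements are redrawn on collision, so both
screens can target the same core gene without overwriting each other's
sequence).

What the generator does **not** emulate: read-level artifacts (duplication,
mappability, fragment-length effects), strand-specific binding, correlated
noise between conditions, peak-caller behaviour (E-values are planted, not
computed), and annotation errors. Passing the recovery tests therefore shows
the *logic* of the chain is sound — filters, subtraction, intersection,
distances, classification and bookkeeping — not that the pipeline is robust
to upstream artifacts it never sees.

## A worked example

```{r example}
cfg <- sim_config(seed = 11, n_scaffolds = 8, n_genes_per_scaffold = 15,
                  scaffold_length = 100000, n_specific_peaks = 20,
                  n_shared_peaks = 6, n_core_targets = 8,
                  n_transcripts = 2000, zero_fpkm_fraction = 0.25,
                  n_deg_parasitism = 120, n_deg_viral = 90,
                  n_deg_common = 40)
sim <- simulate_h4_dataset(cfg)
report <- h4_pipeline(sim$expression, sim$peaks, sim$genes,
                      sim$scaffolds, sim$genome)
report
setequal(report$core$gene_id, sim$truth$core_genes)
```

```{r plots, fig.width = 7, fig.height = 4}
plot_physical_map(report$map)
plot_neighborhood_profile(report$profiles[[1]])
```

## Known limitations

* The nearest-gene distance definition (gap), the tie rules, the inclusive
  thresholds and the homogeneity chi-square layout are documented choices
  among defensible alternatives; all are either arguments or confined to
  one function each, and each carries a test so a change is visible.
* The chi-square tests are asymptotic; with very small per-cell counts the
  positional test's size will drift, which is why empty levels are dropped
  with a warning rather than silently.
* The repeat finder targets perfect short tandem repeats only — no
  mismatches, no interrupted or higher-order repeats, no consensus-motif
  discovery, and no functional annotation of motifs against
  transcription-factor databases.
* `contribution_pct` inherits the reference list's composition; it is a set
  ratio, not a causal estimate.
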