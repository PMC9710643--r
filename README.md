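# srmclust

Discovering, clustering and ranking groups of mutually interdependent
columns in protein multiple sequence alignments (MSAs).

## The problem

Aligned sites that co-vary across homologues are interdependent, whether
or not they are proximal in the folded structure: binding pockets,
folding nuclei, or long-range couplings between ordered domains and
intrinsically disordered regions. Structure predictors and contact-based
couplings (DCA-style) concentrate on proximal pairs; srmclust targets
the complementary question -- which *groups* of sites, of any size and
any spatial arrangement, constrain each other -- for researchers
analysing protein families from large MSAs.

## The method

* **Pairwise score.** For two columns $A, B$ the joint symbol counts are
  tabulated and *nullified*: cells involving gaps (`-`, `.`) or unknown
  symbols (`X`, `B`, `Z`, ...) are zeroed and the marginals recomputed, so
  entropies and mutual information are measured only on sequences with
  residues at both sites. The score is the normalized mutual information
  $\mathrm{NMI}(A,B) = I(A;B)/\min\{H(A),H(B)\} \in [0,1]$ (bits,
  plain empirical frequencies), symmetric and invariant to sequence
  order. Perfectly invariant pairs are flagged and scored 1; columns too
  close to invariance to normalise (entropy < `epsilon_inv`, default
  0.05 bits) are excluded and reported.
* **Cluster arithmetic.** For a cluster $Q$, each member's statistical
  redundancy is $SR(i) = \sum_{i'\in Q\setminus\{i\}} \mathrm{NMI}(i,i')$;
  the *mode* $j^\* = \arg\max_i SR(i)$ represents the cluster, and the
  cluster's strength is the statistical redundancy mode
  $\mathrm{SRM} = SR(j^\*)/(|Q|-1) \in [0,1]$, comparable across cluster
  sizes.
* **Two-phase k-modes agglomeration.** Phase I greedily extracts the
  strongest mutually-exclusive column pairs (optionally within
  interleaved "spread" subsets); phase II merges pairs and leftover
  singletons best-first, where the affinity between two entities is the
  NMI of their *modes*, recomputed after every merge. Every intermediate
  cluster is kept, ranked by SRM within its order, and the merge history
  forms a polytree exportable as DOT/GraphML or as PyMOL residue
  selections via reference-sequence renumbering.
* **Null model.** Column-shuffling preserves each column's composition
  and gap structure while destroying inter-column dependence; a
  selection-matched null scan plus Welch's t-test quantifies how far the
  discovered SRM distributions sit above chance.

## A worked example

```r
library(srmclust)

sim <- generate_planted_msa(
  n_seqs = 400, n_cols = 12,
  groups = list(list(columns = c(1, 2), noise = 0.1),
                list(columns = 4:6, noise = 0.15)),
  gap_rate = 0.05, seed = 3)
scan <- srm_scan(sim$alignment, min_nmi = 0.3, min_merge_nmi = 0.3)
scan$ranked
#>   order rank       srm mode members step
#> 1     2    1 0.7729092    1     1;2    1
#> 2     2    2 0.6338533    4     4;5    2
#> 3     3    1 0.6244965    4   4;5;6    3
```

The planted pair `{1,2}` is the top order-2 cluster (SRM 0.77 = its
NMI); the planted triple is assembled in phase II from the pair `{4,5}`
plus column 6 and is the only order-3 cluster, with a lower SRM (0.62) --
larger clusters are held to a per-pair average, so their scores decay
with noise. Thresholds of 0.3 sit above the finite-sample noise floor at
400 sequences (chance-level NMI ~0.18 here); see the vignette for how to
pick them. Against the column-shuffled null:

```r
null_check(sim$alignment, orders = 2, seed = 5,
           min_nmi = 0.3, min_merge_nmi = 0.3)
#>   order real_mean ... null_mean   null_lo   null_hi        t          p
#> 1     2 0.7033813 ... 0.1777585 0.1333591 0.2221579 7.336876 0.06892782
```

(The p-value is large here only because the real side has just two
order-2 clusters; at realistic scale the separation is decisive, e.g.
t > 10, p < 1e-9 in the desk-scale experiment below.)

A shell front end wrapping the same functions lives at
`inst/scripts/srmclust.R` with `scan`, `synth` and `nullcheck`
subcommands.

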