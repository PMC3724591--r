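# protplot

Lollipop plots of protein mutations, with domain architecture, PTM
sites and alignment-based conservation — from R or the command line.

Sequencing studies yield lists of amino-acid changes; whether those
changes scatter across a protein or cluster inside a particular region
is often the first biologically meaningful question, and it is far
easier to answer from a picture than from a table. The textbook
example is the RET receptor tyrosine kinase: disease mutations overall
are distributed along the whole protein, but the subset causing
Multiple Endocrine Neoplasia 2A piles up on a few extracellular
cysteines just before the transmembrane segment. protplot draws that
kind of figure deterministically, annotates every variant against
domains and PTM sites, and scores per-position conservation from a
multiple sequence alignment.

## The conservation score

For a user-designated reference row of an alignment, each reference
residue *p* sits in one alignment column, and

&nbsp;&nbsp;&nbsp;&nbsp;*s* = *n* / *t*

where *t* is the number of non-reference sequences and *n* the number
of them whose residue at that column equals the reference's. *s* ranges
over [0, 1]: 0 means no other sequence matches the reference there, 1
means all do. The reference never counts itself, *t* is constant across
positions, and a gap in another sequence counts as a mismatch — see the
methods vignette (`vignettes/protplot-methods.Rmd`) for why.

## Worked example

```r
library(protplot)

# Synthetic inputs shaped like the RET case study: four domains, a broad
# mutation set, and the clustered MEN2A-like cysteine substitutions.
fx <- make_ret_like_fixture()

# A simulated 7-sequence ortholog alignment and its conservation profile.
cfg <- fixture_config(protein_length = fx$context$length,
                      n_alignment_sequences = 7, seed = 42)
profile <- conservation_scores(simulate_alignment(cfg), context = fx$context)

# Which domains and PTM sites do the clustered mutations hit?
ann <- annotate_mutations(fx$mutations_secondary, fx$domains, fx$ptms, profile)
ann[, c("position", "ref", "alt", "is_ptm_site", "conservation")]
#>   position ref alt is_ptm_site conservation
#> 1      609   C   R       FALSE    1.0000000
#> 2      611   C   Y       FALSE    1.0000000
#> 3      618   C   S       FALSE    1.0000000
#> 4      620   C   R       FALSE    0.8333333
#> 5      630   C   F       FALSE    0.8333333
#> 6      634   C   W       FALSE    1.0000000

spec <- plot_spec(fx$context, fx$mutations,
                  mutations2 = fx$mutations_secondary,
                  domains = fx$domains, ptms = fx$ptms, profile = profile,
                  show_score = TRUE,
                  track_labels = c(primary = "All", secondary = "MEN2A"))
spec
#> <plot_spec> RET-like (1114 aa), window 1..1114, 40 mutation(s) + 6 secondary

render(spec, "ret_full.svg")                    # whole protein
render(zoom_view(spec, 580, 700), "ret_zoom.svg")  # the cluster region
```

The annotation table reads: none of the six clustered cysteines falls
inside an annotated domain (they sit between Cadherin, ending at 270,
and the Transmembrane segment starting at 636 — "near" it, not in it),
none coincides with a PTM site, and each is at a highly conserved
position of the simulated alignment (s = 5/6 or 6/6). The zoomed
figure shows the six labeled lollipops (C609R … C634W) packed against
the left edge of the Transmembrane box.

The same pipeline runs from a shell via the installed CLI wrapper
(`inst/cli/protplot`), e.g.

```sh
protplot fixture --out demo --seed 7
protplot plot --mutations demo/mutations.tsv --mutations2 demo/mutations2.tsv \
  --architecture demo/architecture.tsv --ptm demo/ptm.tsv \
  --alignment demo/alignment.fasta --reference-id reference \
  --length 1114 --name RET-like --show-score --zoom 580:700 \
  --out ret_zoom.svg --table annotation.tsv
```

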