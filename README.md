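# termscout

Candidate search-term mining for systematic review search strategies.

Information specialists developing Boolean searches for systematic
reviews need to decide *which* free-text terms and MeSH headings to
put in the query. The **objective approach** derives them
statistically: starting from a *test set* of records already known to
be relevant, every term from titles, abstracts and keyword fields is
ranked by how strongly it is overrepresented relative to a *population
set* — a random background sample of database records. termscout
implements that workflow as an R library plus a small command-line
tool, for information specialists and methods researchers who want the
analysis scriptable, reproducible, and free of GUI lock-in.

## The statistic

For a term found in $x$ of the $n$ test-set records, with document
probability $p_0$ in the population set, the overrepresentation score
is the normal approximation of the binomial test (no continuity
correction):

$$ z = \frac{x - n\,p_0}{\sqrt{n\,p_0\,(1-p_0)}} $$

Terms with $z \ge 20$ are flagged as candidate search terms. Terms
absent from the population set cannot be tested and receive the
sentinel $z = 10000$ — maximally discriminating, always a candidate.
All counts are document frequencies (records containing the term), and
MeSH descriptors, qualifiers (subheadings) and free text are scored
against their own matched population maps.

Around the ranking, the package provides the full workflow:
reproducible 2:1 development/validation splits of the test set with a
reported seed, PMID lists in Ovid `.ui.` syntax, keyword-in-context
views, a 2-word skip-gram table for choosing proximity operators, and
CSV export in the Western European dialect (semicolon separator, comma
decimals) or a standard dialect.

## Worked example

A small synthetic test set (18 records about breast-cancer screening)
and a synthetic 1000-record population model ship with the package:

```r
library(termscout)
ts  <- read_ris(system.file("extdata", "testset_synthetic.ris",
                            package = "termscout"))
pop <- load_population_model(system.file(
  "extdata", "population_synthetic.tsv", package = "termscout"))

split <- split_records(ts, seed = 42)
split
#> <split_result> development 12 / validation 6 (ratio 2:1), applied random seed 42

freetext_table(split$development, pop)
#> # A tibble: 8 × 6
#>   term        documents documents_pct         z term_frequency is_candidate
#>   <chr>           <int>         <dbl>     <dbl>          <int> <lgl>
#> 1 mammography         7          58.3 10000                 13 TRUE
#> 2 screening          11          91.7    40.8               24 TRUE
#> 3 breast              8          66.7    14.2               16 FALSE
#> 4 recall              5          41.7    12.9                5 FALSE
#> 5 women               9          75       6.72              15 FALSE
#> 6 cancer             10          83.3     5.89              21 FALSE
#> 7 patients            8          66.7     0.121             11 FALSE
#> 8 study               7          58.3    -0.882              7 FALSE
```

Reading the table: "screening" appears in 11 of the 12 development
records (91.7 %) but in only 0.6 % of the population, so its
overrepresentation score (z = 40.8) clears the candidate cut-off of
20. "mammography" never occurs in the population sample at all and
gets the 10000 sentinel. "cancer" is frequent in the test set *and*
in the background, so despite 83 % document coverage it is not a
useful discriminator (z = 5.9). `documents_pct` doubles as the
single-term relative recall: searching "screening" alone would
retrieve 91.7 % of the development set.

The same scoring applies to controlled vocabulary, and the validation
set can be re-retrieved in Ovid to verify candidate terms:

```r
mesh_table(split$development, pop, mini_mesh_dictionary())
#> # A tibble: 6 × 5
#>   term                      documents documents_pct        z is_candidate
#> 1 Early Detection of Cancer         5          41.7 10000    TRUE
#> 2 Mammography                       6          50      24.3  TRUE
#> 3 Mass Screening                    7          58.3    22.4  TRUE
#> 4 Breast Neoplasms                  9          75      18.1  FALSE
#> 5 Female                            8          66.7     1.89 FALSE
#> 6 Humans                           12         100       1.46 FALSE

pmids_to_ovid(split$validation)
#> [1] "(100003 or 100006 or 100011 or 100012 or 100015 or 100018).ui."
```

Context views support phrase building — `kwic(ts, "breast cancer",
window = 2)` lists every occurrence with two words of context, and
`skipgram_table(ts)` counts ordered word pairs at skip distances 0–2
for proximity-operator searches.

### Command line

The same workflow is available from a shell via the bundled wrapper:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "termscout.R", package = "termscout"))')
Rscript "$cli" split testset.ris --seed 42
Rscript "$cli" freetext testset.ris --population pop.tsv > freetext.csv
Rscript "$cli" build-population background.ris --out pop.tsv
```

CSV tables go to stdout in the Western European dialect
(`--dialect standard` switches to comma/dot); logs go to stderr.

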