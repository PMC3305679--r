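# dfid — dosage-form identification and normalization in drug monographs

Consumer-level drug monographs state a drug's dosage forms only in prose
("*comes as a tablet to take by mouth*"), while drug terminologies carry
them as standardized concepts (*Oral Tablet*, *Injectable Solution*). A
drug's dosage form is not a detail: the same ingredient as an ophthalmic
solution and as an oral tablet is, for most purposes, two different drugs.
`dfid` is for informaticians who need to link free-text monographs to
terminology-coded drug resources: it identifies dosage-form statements in
monograph text and normalizes them to concepts in a dosage-form hierarchy.

## Method

The terminology is a set of dosage-form concepts with dotted **tree
numbers** encoding specificity ("F4" Solid → "F4.23" Tablet → "F4.23.1"
Oral Tablet); concept *a* is an ancestor of *b* iff a tree number of *a*
is a proper dotted-segment prefix of one of *b*'s. For a monograph with
title terms *{t₁ … t_N}*, the pipeline:

1. splits the title at the leftmost route marker into ingredient
   *I = {t₁ … t_(q−1)}* and route *R = {t_q … t_N}* (e.g. "Diclofenac
   Ophthalmic");
2. extracts evidence sentences *E = {e₁ … e_k}* from the usage sections
   with five patterns — P1 "come as", P2 "come in", P3 sentence starts
   with an ingredient term, P4/P5 sentence starts with a determiner +
   "medication"/"drug";
3. rewrites lay route phrases to route vocabulary ("by mouth" → "oral");
4. appends the title route *R* to each sentence (so "It also comes as a
   solution." under the title "Propranolol Oral" can match *Oral
   Solution*);
5. reduces each sentence to a bag of unique Porter stems and matches every
   concept whose name stems are all present (*Oral Solution* ⇔ {"oral",
   "solut"});
6. pools candidates across sentences and keeps only the **most specific**
   set *D* (no reported concept is an ancestor of another).

Predictions are scored per monograph against a reference set *F* — a
hand-annotated gold standard, or a **silver standard** built automatically
by mapping the monograph's listed brand names through branded-drug records
to their dosage forms — with

&nbsp;&nbsp;Precision = |D ∩ F| / |D|,&nbsp;&nbsp;Recall = |D ∩ F| / |F|,
&nbsp;&nbsp;F = 2PR / (P + R),

macro-averaged over monographs (mean, SD, median, IQR). A dictionary-lookup
baseline (unstemmed concept terms in the usage section, no rules) is
included for comparison, and a seeded synthetic-corpus generator produces
monographs, mini terminologies, branded-drug tables, and gold labels with
known ground truth. The methods vignette
(`vignettes/dosage-form-identification.Rmd`) documents the design choices
and their limits.

## Worked example

```r
library(dfid)

tree <- load_terminology(
  data.frame(concept_id = c("ORAL_TAB", "ERT", "ORAL_CAP", "ERC"),
             name = c("Oral Tablet", "Extended Release Tablet",
                      "Oral Capsule", "Extended Release Capsule")),
  data.frame(concept_id = c("ORAL_TAB", "ERT", "ORAL_CAP", "ERC"),
             tree_number = c("F4.23.1", "F4.23.1.5", "F4.24.1", "F4.24.1.1")))

m <- monograph("darifenacin", "Darifenacin", sections = list(
  "How should this medicine be used?" =
    "Darifenacin comes as an extended-release (long-acting) tablet to take by mouth."))

res <- identify_dosage_forms(m, tree)
res
#> <identification_result> darifenacin: {ERT}

res$evidence
#> # A tibble: 2 × 4
#>   concept_id pattern section_name                      sentence
#>   <chr>      <chr>   <chr>                             <chr>
#> 1 ORAL_TAB   P1      How should this medicine be used? Darifenacin comes as an …
#> 2 ERT        P1      How should this medicine be used? Darifenacin comes as an …

prf(res$dosage_forms, "ERT", monograph_id = "darifenacin")
#> # A tibble: 1 × 7
#>   monograph_id precision recall f_measure n_predicted n_reference n_correct
#>   <chr>            <dbl>  <dbl>     <dbl>       <int>       <int>     <int>
#> 1 darifenacin          1      1         1           1           1         1
```

The sentence is a P1 ("comes as") evidence sentence; after translating
"by mouth" to "oral", the stem bag matches both *Oral Tablet* and
*Extended Release Tablet* (see `res$evidence`), and the specificity filter
keeps only the child concept — so the prediction matches the annotation
exactly and all three metrics are 1.

Corpus-level runs use `identify_corpus()` + `macro_evaluate()`, or the
command-line wrapper:

```sh
Rscript inst/scripts/dfid.R fixtures --seed 1 --n 50 --out corpus/
Rscript inst/scripts/dfid.R identify --monographs corpus/monographs \
    --concepts corpus/terminology/concepts.tsv --tree corpus/terminology/tree.tsv \
    --out pred.tsv
Rscript inst/scripts/dfid.R evaluate --pred pred.tsv --standard corpus/gold.tsv \
    --out summary.tsv
```

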