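---
title: "Identifying and normalizing dosage forms in drug monographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and normalizing dosage forms in drug monographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfid)
```

## The problem

A drug's dosage form — oral tablet, ophthalmic solution, transdermal patch —
is part of what defines the drug: the same ingredient in different forms has
different uses, routes, and pharmacokinetics. Consumer-level drug monographs
describe dosage forms only in running prose ("*comes as a tablet to take by
mouth*"), while structured drug terminologies carry them as standardized
concepts. `dfid` bridges the two: it reads monograph XML, finds the sentences
that state dosage forms, and normalizes them to concepts in a dosage-form
hierarchy, so that free-text monographs can be linked to terminology-coded
resources.

The method is deliberately rule-based. Monograph prose is tightly
editorially controlled — titles follow an "ingredient + route" pattern and
usage statements recur in a handful of templates — so closed-class rules are
both transparent and effective there, at the price of being tailored to this
genre (see *Limitations*).

## The dosage-form hierarchy

The terminology is a set of concepts, each carrying one or more dotted
**tree numbers** ("F4" Solid, "F4.23" Tablet, "F4.23.1" Oral Tablet).
Specificity is encoded entirely in the numbers: concept *a* is an ancestor
of concept *b* when some tree number of *a* is a proper dotted-segment
prefix of some number of *b*. Comparison is by whole segments — "F4.2" is
not a prefix of "F4.23". A concept may own several numbers, which gives it
several parents; an extended-release enteric-coated tablet sits under both
the enteric-coated ("F4.23.1.4.1") and the extended-release ("F4.23.1.5.1")
tablet branches. Storing the order in the numbers, with no separate parent
pointers, keeps multi-parent membership and ancestor queries uniform.

The relation is a strict partial order (irreflexive, transitive), and the
identification output is always an **antichain**: no reported concept is an
ancestor of another. The test suite checks the order axioms and compares
the antichain filter against an exhaustive pairwise oracle on every subset
of an 8-concept tree.

## The identification pipeline

For one monograph:

1. **Title segmentation.** The title is tokenized on whitespace and split
   at the leftmost *route marker* (nasal, ophthalmic, otic, oral, rectal,
   vaginal, topical, transdermal, injection, inhalation by default):
   everything before the marker is the ingredient `I`, the marker and what
   follows is the route `R`. Matching is whole-token and case-insensitive;
   a marker in first position is kept as ingredient, since a title is never
   pure route. The marker list is a plain-text config file
   (`inst/extdata/route_markers.txt`) because any fixed list is an
   editorial choice, not an algorithmic one.

2. **Evidence extraction.** The two usage sections ("How should this
   medicine be used?" — either the "medicine" or "medication" spelling —
   and "About your treatment") are split into sentences, and each sentence
   is tested against five patterns: P1 contains "come as" (variants of
   "come" allowed), P2 contains "come in", P3 begins with an ingredient
   term from the title, P4 begins with a determiner plus "medication(s)",
   P5 likewise for "drug(s)". Precedence P1 > P2 > P3 > P4 > P5 is
   first-match-wins; it affects only the provenance label, since all
   evidence sentences are processed identically downstream. The
   "subject of the sentence" tests (P4/P5) are implemented as anchored
   determiner + keyword at the sentence start — a deliberately parser-free
   approximation that cannot fire on objects ("Take the medication daily"
   does not match).

3. **Route translation.** Lay route expressions are rewritten to the route
   vocabulary of concept names: "by mouth" → "oral", "into the ear" →
   "otic", "on the skin" → "topical", "in the eye" → "ophthalmic", and so
   on. Rules apply case-insensitively at word boundaries,
   longest-phrase-first so overlapping phrases cannot be half-replaced.
   The shipped rule set (`inst/extdata/translation_rules.tsv`) includes
   surface variants ("in the eyes", "to the eyes") plus "into the vagina"
   → "vaginal" and "by injection" → "injectable", so that vaginal and
   injectable forms are expressible in lay prose; like the markers, the
   rules are data, not code.

4. **Enrichment.** The title's route terms are appended (lowercased) to
   every evidence sentence. In a monograph titled "Propranolol Oral", the
   sentence "It also comes as a solution or concentrate." becomes
   matchable against *Oral Solution* only through this step. Enrichment is
   unconditional — matching is set-based, so appending a route that is
   already present is harmless.

5. **Stem-bag matching.** The translated, enriched sentence is lowercased,
   split on whitespace with hyphens and slashes as separators
   ("extended-release" contributes "extended" and "release"), stripped of
   punctuation, Porter-stemmed, and deduplicated. A concept is matched
   when **all** stems of its name are in the bag — "Oral Solution" needs
   both "oral" and "solut". Matching is therefore monotone: adding words
   never removes a match.

6. **Specificity filter.** Candidates from all evidence sentences are
   pooled per monograph and ancestors of other candidates are removed.
   "Darifenacin comes as an extended-release (long-acting) tablet to take
   by mouth" matches both *Oral Tablet* and *Extended Release Tablet*;
   only the child is reported.

The bag-of-words representation has a known failure mode that the package
reproduces on purpose: in "…comes as a tablet and an extended release
capsule to take by mouth", the modifier "extended release" also combines
with "tablet", so *Extended Release Tablet* is reported alongside the
correct *Extended Release Capsule*, and precision and recall against the
two annotated forms are both 0.5. This is the documented cost of ignoring
token positions (step 5), and the acceptance checks assert it rather than
hide it.

A **baseline** is included for comparison: whole-section, case-insensitive
lookup of *unstemmed* concept-name terms in the usage section, with no
segmentation, translation, enrichment, or filtering. It is the natural
dictionary-lookup control for measuring what the rules contribute.

## Reference standards and evaluation

A **gold standard** is a hand-annotated table of (monograph, concept)
pairs. A **silver standard** is derived automatically: each brand name
listed in a monograph's "Brand names" section is matched (case-insensitive,
trademark glyphs ® ™ stripped, no fuzzy matching) against branded-drug
records that link a brand to its dosage form, and the linked forms are
unioned. A monograph with no brand section, no mappable brand, or no
dosage-form link on its matched records is *excluded* with that reason
rather than scored; a partially mapped brand list still yields an entry.
Fuzzy brand recovery is intentionally absent — unmapped brands are treated
as an observable failure mode, not silently repaired.

Per monograph, precision is `|D ∩ F| / |D|` and recall `|D ∩ F| / |F|`
(predicted set `D`, reference set `F`), F the harmonic mean. Corpus scores
are **macro averages** (mean over monographs), reported with SD, median,
and IQR. Conventions, chosen once and tested: an empty prediction scores
P = R = F = 0 — a monograph where the method finds nothing (e.g. a vaccine
monograph with no usage section) counts as a failure, not a skip; F = 0
when P + R = 0; SD uses the sample (n−1) form; IQR is Q3 − Q1 with
linear-interpolation quantiles (R type 7). Exact concept-id match is the
primary scoring mode; a hierarchical-credit mode (ancestor/descendant
counts as a match) is available behind a flag for sensitivity analysis
and is off by default.

## The synthetic corpus generator

Real monograph corpora and full terminology releases are licensed, so the
package generates its own test corpora with known ground truth
(`fixture_spec()`, `generate_terminology()`, `generate_monographs()`,
`write_fixture_corpus()`). The mini terminology always contains a
19-concept backbone (the solid/tablet branch with oral, vaginal, chewable,
enteric-coated, and extended-release tablets, a multi-parent
extended-release enteric-coated tablet, the capsule and solution branches,
ointments), optionally extended with further leaf forms. Monographs get
1–3 planted leaf forms — 1/2/3 with probability 0.5/0.4/0.1, mean 1.6,
close to the ~1.55 forms per monograph typical of annotated consumer
monographs — one evidence sentence per planted form instantiated from the
P1–P5 templates, distractor prose, and a brand section consistent with the
generated branded-drug table.

Three knobs define the study conditions: `route_noise` (probability a
sentence uses a lay route phrase needing translation; default 0.5),
`brand_dropout` (probability a monograph omits its brand section; default
0), and `distractor_rate` (probability of each distractor sentence;
default 0.5). All output is a pure function of the spec including its
seed; the generator uses a private RNG stream and leaves the session RNG
untouched.

Two generator choices matter for interpreting results. Planted sets are
**antichains**: the specificity filter would necessarily delete a planted
ancestor of another planted form, so a non-antichain target is
unrecoverable by construction — the generator does not set impossible
tasks. And each planted form gets its **own** sentence, so noise-free
corpora avoid the cross-product ambiguity above; that hard case is covered
separately by the worked-example tests. Consequently, perfect recovery on
noise-free fixtures (asserted in the test suite on a 200-monograph corpus)
demonstrates that the pipeline machinery is lossless under ideal
conditions — not that real prose, with its unmodeled phrasing variety,
would score 1.0. The translation-rule ablation (all-lay routes, rules
disabled, recall strictly below 1) shows the direction of the rules'
contribution, again under generated conditions.

Test problem sizes — a 200-monograph corpus for recovery, all 256 subsets
of the 8-concept tree, 1000 random bags, 10000 random prediction pairs —
were chosen as the smallest sizes that exercise every code path and
exhaust the small combinatorial spaces.

## Degenerate inputs and tie-breaking

* A monograph with no evidence sections yields an empty result, never an
  error; it scores zero when a reference entry exists.
* Mutually incomparable candidates are all retained — multiple dosage
  forms per monograph are expected.
* A tree number assigned to two concepts is a load error (data defect,
  not a tie to resolve); so are unknown concept references, malformed
  numbers, and concepts without numbers.
* An empty reference set at scoring time raises an error: standards
  construction is responsible for excluding such monographs, and silently
  scoring them would corrupt the macro average.
* Sentence splitting is a rule (`[.?!]` + space + capital, abbreviation
  stop-list) rather than a statistical model; monograph prose is simple
  declarative text and the splitter is validated against recorded
  boundaries.

## Limitations

* Token positions are ignored; forms and routes in one sentence associate
  freely (the cyclobenzaprine failure mode above).
* The rules target this monograph genre. The title segmenter assumes
  "ingredient + route"; applying the pipeline to other document types
  would need new patterns.
* The shipped marker and translation lists are starting points, editable
  as config; no claim of completeness is made.
* Brand matching is exact; misspelled or reformatted brand names become
  `BRAND_UNMAPPED` exclusions.
* The generator emulates template phrasing, not the full variety of real
  prose: no anaphora across sentences, no strength/frequency clutter
  inside evidence sentences, no section-structure irregularities.
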