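# MolConverse

Desk-scale toolkit for **conversational molecular design**: a user describes
a target molecule over several turns of natural language and a model
proposes SMILES structures after every turn, or — in the opposite direction —
generates a readable paragraph of property descriptions for a given
molecule. The package is aimed at researchers who want to study the *data
contracts and evaluation* of this task end to end without GPU-scale
pretraining or external downloads: it builds multi-turn dialogue corpora
from molecule–description pairs, generates knowledge-injection pretraining
tasks, attaches retrieved SMILES prompts with answer-leakage removal, trains
a small twin encoder–decoder sequence-to-sequence model, and scores both
task directions with the field's standard metric suite.

## What is inside

* **Dialogue construction.** A description *T* for molecule *M* is split
  into sentences and reversed, so cumulative turn text *T₁…Tₖ* grows from
  general properties to fine structure. Each non-final turn *k* receives an
  intermediate target molecule *Mₖ* chosen among five generated candidates
  subject to a fingerprint similarity gate

  > 0.5 < Tanimoto(fp(*Mₖ*), fp(*Mₙ*)) < 1

  on path fingerprints against the final answer *Mₙ* — similar enough to
  stay on topic, never equal (that would leak the answer). Items with one
  turn, or with "-" in a sentence (systematic nomenclature spells out the
  structure), are rejected with logged reasons.
* **Knowledge tasks.** Span-corruption masked language modelling on text and
  on atom-tokenized SMILES; name↔SMILES mapping correlation via
  longest-match lexicon scanning; experimental-property QA over 15 property
  types; spatial-structure QA (atom neighbours, aromaticity, ring
  membership) answered from the parsed graph. Property and spatial targets
  are machine-verified against the molecular graph.
* **Plugin prompting.** Entities in the input text are annotated with their
  SMILES and appended as hints; any hint whose *canonical* SMILES equals an
  answer molecule is forcefully removed.
* **Twin seq2seq model.** Two independent GRU encoder–decoder parameter sets
  with dot-product attention over a joint vocabulary — one decodes SMILES,
  one text — trained with task prefixes, mixed-task batches, dialogue
  fine-tuning, dual augmentation and beam-search top-3 generation. Pure R,
  hand-derived gradients (checked against finite differences),
  bit-reproducible given a seed.
* **Metrics.** Generation: exact match and hit@3 on canonical SMILES,
  character BLEU, Levenshtein distance, and path/MACCS/Morgan fingerprint
  Tanimoto similarity. Understanding: BLEU-2/4, ROUGE-1/2/L, METEOR
  (exact-matching variant).
* **Synthetic corpus generator.** Molecules from a closed functional-group
  grammar with template descriptions whose every sentence carries a
  verification predicate, plus a name lexicon and property table — so every
  stage above is testable with known ground truth.

Chemistry plumbing (canonical SMILES, fingerprints) runs on OpenBabel via
the Bioconductor package ChemmineOB; SMILES validity and the atom/bond/ring
graph come from the package's own strict parser.

## Worked example

```r
library(MolConverse)

corp  <- genCorpus(30, seed = 5)
built <- buildDialogues(corp, config = dialogueConfig(retainLowSim = 0),
                        seed = 11)
length(built$dialogues)        # 20  (10 records rejected by the filters)
table(built$rejections$reason) # no_candidate: 10

d <- built$dialogues[[1]]
dialogueTurns(d)[, c("k", "expectedSmiles")]
#>   k expectedSmiles
#> 1 1         C(C)CC
#> 2 2         CCC(C)
#> 3 3         CCC(C)
#> 4 4            CCC
tanimotoToRef(dialogueTurns(d)$expectedSmiles[1:3], finalSmiles(d))
#> 0.667 0.667 0.667   # every intermediate strictly inside (0.5, 1)

# train the molecule route on 20 dialogues and score exact match
dias  <- built$dialogues[1:20]
exs   <- dialogueExamples(dias)
model <- converseModel(modelVocabulary(exs),
                       converseConfig(hidden = 72, layers = 2, seed = 3))
model <- trainModel(model, exs, steps = 800, batchSize = 26, seed = 9,
                    sampler = "epoch")
rep <- evaluateDialogues(model, dias)   # final-turn predictions, top-3 beam
aggregateMetrics(rep)[c("em", "hit3")]
#> em hit3
#>  1    1
```

The exact-match score is the fraction of dialogues whose final-turn rank-1
prediction is canonically identical to the answer molecule; hit@3 allows any
of the three beam candidates. Intermediate-turn items can be scored with
`evaluateDialogues(..., turns = "all")`.

A command-line front end for the seven pipeline stages (synth, knowledge,
dialogues, prompts, train, augment, evaluate) ships in
`inst/cli/molconverse`:

```sh
Rscript inst/cli/molconverse synth --out run1 --n 50 --seed 1
Rscript inst/cli/molconverse dialogues --out run1 --seed 1
```

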