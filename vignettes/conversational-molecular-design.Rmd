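---
title: "Conversational molecular design with MolConverse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversational molecular design with MolConverse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

In conversational molecular design a user describes a target molecule over
several turns of natural language, refining the requirements as the
conversation progresses, and a model proposes candidate structures in SMILES
notation after every turn. Two directions matter: *molecule understanding*
(given a SMILES, generate a readable paragraph of property descriptions) and
*molecule generation* (given the accumulated description — and optionally the
previous candidate, supplied as the sentence "It looks like ⟨SMILES⟩." —
generate the molecule). MolConverse implements the full desk-scale apparatus
for studying this task: dialogue-corpus construction from molecule–description
pairs, knowledge-injection pretraining data, retrieval-augmented prompting
with answer-leakage removal, a small twin encoder–decoder model, and the
evaluation suite used for both directions.

## Dialogue construction

The builder starts from parallel records ⟨molecule M, description T⟩. Curated
molecule descriptions run from fine structural detail to general properties,
so the description is split into sentences and the order reversed: cumulative
turn text then grows from "general" to "specific", which is how a user would
iteratively pin down a target. For every non-final turn the builder asks a
candidate generator for five molecules matching the cumulative text and keeps
one whose path-fingerprint Tanimoto similarity to the final answer lies
strictly inside (0.5, 1). The open interval is the point: similarity 1 would
hand the user the final answer early (information leakage), similarity at or
below 0.5 would derail the conversation. Items whose description yields a
single turn are dropped, as are items containing "-" in a sentence — systematic
chemical nomenclature (e.g. IUPAC names) contains hyphens and spells out the
structure, which again leaks the answer. A configurable fraction
(`retainLowSim`, default 0.05) of turns whose gate comes up empty instead keep
their most similar candidate, so a few low-similarity conversations survive
for variety; such retained turns still exclude exact matches of the answer.

Two open points were settled as follows. The hyphen rule is applied per item
(one hyphenated sentence rejects the record), the stricter reading; and
retained low-similarity turns bypass only the lower bound, never the upper
(the upper bound exists to prevent leakage, which the variety argument does
not override).

The candidate generator is pluggable. The default proposes structural
perturbations of the final answer (atom substitution, chain extension,
terminal deletion, branch insertion) ordered by similarity — a deliberately
simple stand-in for a large text-to-molecule captioning model, adequate
because the gate, not the generator, defines the dataset contract. Any
external generator can be substituted through the `candidateGenerator`
argument of `buildDialogue()`.

## Knowledge-injection pretraining tasks

Six task types, each tagged with a prefix token so one multi-task model can
route behaviour:

* **Span-corruption MLM** on descriptions (word tokens) and on SMILES
  (atom-level tokens, so a mask never splits `Cl` or a bracket atom). Spans
  are replaced by sentinels; the target replays each sentinel followed by the
  hidden tokens. Defaults: mask rate 0.15, mean span length 3, matching
  common span-corruption practice. The masked-token count is guaranteed
  within one token of `round(rate × length)`.
* **Mapping correlation**, both directions: chemical names detected in text
  (longest-match, non-overlapping scan over a local name→SMILES lexicon;
  a stand-in for named-entity recognition plus database retrieval) produce
  text→SMILES records listing all mentions in order, and SMILES→name records
  per mention.
* **Experimental property QA**: for each property row (15 property types:
  solubility, color, corrosivity, odor, physical state, melting point,
  boiling point, density, flash point, stability, viscosity, vapor pressure,
  acidity, flammability, refractive index) a record asks for the property of
  a SMILES and answers with the recorded value in a sentence.
* **Spatial structure QA**: records query a single atom for its bonded
  neighbours, aromaticity, or ring membership, answered from the parsed
  molecular graph.

Property and spatial targets are *machine-checkable*: `factCheckKnowledge()`
re-derives every answer from the graph (or the property table) and the test
suite requires a 100% pass rate. Task prefix strings, mixture weights and the
mask rate are not canonical anywhere, so all are configuration with the
defaults above; batches reproduce the task mixture to within one example.

## The synthetic corpus

Everything above is testable only with ground truth, so the package generates
its own corpora. Molecules come from a closed grammar — alkane/alcohol/amine/
carboxylic-acid chains of 1–8 carbons, optional methyl branch, optional
benzene, cyclopropane or cyclohexane ring, optional halogen — roughly a
thousand distinct structures, weighted so that rings appear in about half the
molecules. Descriptions are assembled from an enumerated template registry
(`sentenceTemplates()`, also listed in `inst/extdata/sentence_templates.tsv`);
every template carries a verification predicate, which is what makes the
"no un-derivable facts" property testable rather than aspirational. Sentences
are ordered structural-first/general-last to mirror curated corpora; 2–6
sentences per record, 3–15 property rows per molecule, and a deterministic
pseudo-name per molecule (stem+stem+suffix from closed word lists). The names
never appear in descriptions, so synonym masking and the leakage filters are
exercised end to end with known answers.

What the generator does *not* emulate: the linguistic diversity of real
curated prose (sentences here come from a small closed set, so distinct
molecules can share their most general sentences), IUPAC nomenclature,
stereochemistry, charged/multi-fragment species beyond simple ions, and
macromolecules. Consequences for interpretation: passing tests demonstrate
the correctness of the construction algorithms, filters and training loop
mechanics — not that the model generalizes to real chemical language. One
knock-on effect is visible in training: first-turn texts (one general
sentence) collide across molecules, so first-turn items are intrinsically
ambiguous; evaluation therefore scores the final answer of each dialogue,
where cumulative text plus the previous-molecule sentence is distinctive —
the same convention the task's headline exact-match numbers use, with
intermediate turns reported separately.

## Chemistry layer

SMILES strings are parsed by the package's own strict reader into a
heavy-atom graph (parse-order 0-based indices, implicit hydrogens), with
smallest-set-of-smallest-rings perception and aromaticity flags; six-membered
C/N rings written in Kekulé form with alternating single/double bonds are
perceived aromatic. The strictness matters because the underlying toolkit
(OpenBabel, via ChemmineOB) silently repairs malformed SMILES — unacceptable
when invalid model output must score zero rather than "whatever the repair
parses as". Canonicalization and fingerprints are delegated to OpenBabel:
`path` (FP2; linear fragments up to 7 atoms, 1024 bits) for the similarity
gate and the RDK-style similarity column, `maccs` (166 structural keys) and
`morgan` (ECFP4, circular radius 2, 4096 bits). A string counts as valid only
if the parser accepts it *and* the toolkit can canonicalize it. Tanimoto
similarity of two all-zero fingerprints (possible for single-atom molecules
under the path scheme) is defined as 0 with a warning — the conservative
choice for scoring.

## The twin model

Two fully independent encoder–decoder parameter sets over a shared joint
vocabulary: one decodes SMILES (molecule route), the other text
(understanding route); routing is by the target language of each task, which
is what "twin" buys — molecule syntax and English never compete for the same
decoder. A configuration flag can share the embedding tables; the default
keeps the sets fully independent. Each route is a batched GRU encoder–decoder
with dot-product attention, written in plain R matrix arithmetic with a
hand-derived backward pass (verified against finite differences in the test
suite) and Adam with global-norm clipping. At desk scale this replaces the
original study's large pretrained transformer backbone; it exercises the
identical data contracts — task prefixes, mixed-task batches, dialogue
fine-tuning with teacher forcing, dual augmentation, beam-search top-3
generation — at a size a laptop CPU trains in minutes.

Numerical and schedule choices worth recording:

* Encoder batches are left-padded and the hidden state is hard-reset to zero
  at pad positions, so a padded training batch computes *exactly* the states
  an unpadded inference pass computes. Without the reset the model learns
  pad-conditioned encoder states and greedy decoding degrades subtly.
* Attention masks padded positions; the decoder is right-padded under a loss
  mask; loss is the mean over unmasked target tokens.
* The decoder uses input feeding: the previous step's attention context is
  added to the next token embedding. Without it the model cannot reliably
  track its position while copying a SMILES span from the source (the
  "It looks like ⟨SMILES⟩." sentence) and edits degenerate into verbatim
  copies or truncations.
* Beam search (width ≥ 3k) ranks finished hypotheses by length-normalized
  log-probability; unnormalized ranking systematically prefers early
  termination and truncates long targets.
* Fine-tuning batches use shuffled-epoch coverage (every example seen
  equally often); sampling with replacement leaves individual examples
  under-trained at memorization scale. Multi-task pretraining instead
  stratifies each batch by task mixture.
* Defaults: hidden/embedding width 64, 2 GRU layers per side, Adam at 5e-3
  with step decay (×0.3 at 50% and 80% of the step budget), gradient clip 5.
  Tokenizers: lowercased word tokens for text, atom-regex tokens for SMILES;
  words inside model inputs that look like SMILES (no lowercase vowels, SMILES
  alphabet, parseable, ≥2 atoms) are atom-tokenized, so "It looks like CCO."
  round-trips.
* Training is bit-reproducible given (seed, config, data): all sampling runs
  through an isolated RNG scope, and the test suite asserts byte-identical
  loss trajectories across reruns.

During dialogue fine-tuning the model is conditioned on the *reference*
previous molecule (teacher forcing); at inference either the reference or the
model's own previous prediction can be fed back (`evaluateDialogues()`
exposes both). Dual augmentation uses the trained understanding route to
describe unlabeled molecules; the resulting pairs are flagged `augmented` so
they can join generation fine-tuning but never an evaluation set.

## Evaluation

Generation: exact match and hit@3 on canonical SMILES (an unparseable
prediction never matches), character-level BLEU-4, raw-string Levenshtein
distance, and Tanimoto similarity under all three fingerprint schemes, each
computed on the rank-1 prediction (the conservative reading where the
convention is unstated). Understanding: lowercased word-token BLEU-2/BLEU-4
(with a 0.5/n floor on zero precisions, the usual small-text smoothing),
ROUGE-1/2/L F-scores, and METEOR in an exact-matching variant without a
synonym dictionary, with the fragmentation penalty counting chunk *breaks*
(`0.5·((chunks−1)/matches)³`) so a verbatim match scores exactly 1 — the
classic chunk-count penalty docks a verbatim match a small amount, which
would break the invariant "gold-as-prediction saturates every metric" that
the evaluation sanity checks rely on. The variant is recorded in the result's
`meteorMatching` attribute.

## Problem sizes used by the checks

The test suite and the acceptance script size their runs as follows: oracle
comparisons at 1000 random pairs; dialogue invariants on a 500-record corpus
(tests) or 300 records (acceptance script); knowledge fact-checking on
240–300 records; overfit recovery on 20 dialogues with the hidden-72
two-layer model for 800 steps plus a hidden-64 understanding model for 600
steps. These sizes keep any single check within a few CPU-minutes while
leaving the measured properties stable across seeds.

## Known limitations

* The SMILES grammar covers the organic subset plus common bracket atoms;
  stereo descriptors are parsed but discarded, and aromaticity perception
  beyond six-membered C/N rings relies on explicit lowercase notation.
* The default candidate generator proposes only local structural edits; gate
  acceptance rates on corpora of very small molecules are correspondingly
  lower (single-atom molecules have empty path fingerprints and rarely pass).
* The model is a toy: no subword fallback for unseen tokens beyond `<unk>`,
  no dropout or label smoothing, and vocabulary fixed at construction time.
* METEOR here is the exact-matching variant; scores are not comparable to
  synonym-aware METEOR implementations.
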