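# fsner

Few-shot biomedical named entity recognition (NER) in R: paraphrase-based
data augmentation with entity localization, multi-scale gated feature
fusion, and a linear-chain CRF decoder, wrapped in a seeded K-shot
evaluation protocol.

## Who this is for

Researchers and tool builders who need a biomedical BIO-tagging system
that works from a handful of labeled sentences (5, 20, 50), want the
augmentation and evaluation protocol to be reproducible to the byte, and
want every neural component testable offline on one CPU. The package
ships a deterministic mock paraphraser and mock contextual encoder so the
entire pipeline — augmentation, training, decoding, scoring — runs with
no network, no GPU and no downloads; a chat-LLM paraphraser and a
pretrained transformer encoder plug in through two small contracts.

## The method

Given tokens $X = (x_1,\dots,x_n)$ with per-token embeddings
$E = \mathrm{Enc}(X)$:

* **Augmentation** — each training sentence is paraphrased several times
  via the prompt "*Original sentence* + Help me rephrase this sentence
  while preserving the original meaning."; the original entity surfaces
  are located in each paraphrase (case-insensitive exact token-sequence
  match), BIO labels are projected onto the located spans, and
  paraphrases in which any entity cannot be located are filtered out.
* **Multi-scale features** — per-token windows of lengths 3/5/7 over $E$,
  a BiLSTM per scale, concatenated into $H$.
* **Dynamic convolution** — $D = \mathrm{Dconv}(E)$, a 1-D convolution
  (kernel 5, pad 2) whose kernel is an input-conditioned convex mixture
  of learned templates.
* **Fusion** — attention with query $\mathrm{Linear}([E,H])$ over the
  projected $[E,H]$ value bank gives $O$; a sigmoid gate blends
  $h = g \odot O + (1-g) \odot D$.
* **Decoding** — a linear layer and a CRF:
  $\hat y = \mathrm{CRF}(\mathrm{Linear}(h))$, trained by maximum
  likelihood, decoded by Viterbi.
* **Protocol** — K sentences sampled per seed, split 8:2 into train/val,
  augmentation applied to train only, entity-level F1 on the full test
  set, mean ± sample sd over five seeds.

See `vignette("fsner-methods")` for assumptions, parameter meanings and
numerical choices.

## Worked example

```r
library(fsner)

spec <- standard_benchmark_spec()     # 40-surface lexicon, 2 types, seed 7
corp <- make_corpus(spec)             # 200 train / 500 test sentences
corp$train_pool[[1]]
#> <tagged_sentence tr1: 7 tokens>
#> treatment/O reduced/O symptoms/O of/O zomirra/B-Disease disease/I-Disease substantially/O

# paraphrase augmentation with the deterministic mock paraphraser
para <- mock_paraphraser(spec)
aug <- augment_dataset(corp$train_pool[1:2], para, multiplier = 3, seed = 1)
aug$n_accepted
#> [1] 6
aug$sentences[[3]]                    # first accepted paraphrase of tr1
#> <tagged_sentence tr1_aug1: 8 tokens>
#> indeed/O care/O eased/O symptoms/O of/O zomirra/B-Disease disease/I-Disease substantially/O

# a small 5-shot experiment (2 seeds, 10 epochs, 100 test sentences)
cfg <- fsner_config(preset = "benchmark", train = list(epochs = 10L))
res <- run_experiment(corp$train_pool, corp$test_set[1:100], cfg,
                      shots = 5L, seeds = c(13L, 42L))
res$summary
#>  shot n_seeds  mean_f1    sd_f1
#>     5       2 24.79888 5.215291
```

The augmented sentence keeps the entity `zomirra disease` verbatim with
its projected labels — the filter guarantees that — while the carrier
words vary. The 5-shot F1 around 25 reflects training on four sentences
for ten epochs; the full benchmark settings (50-shot, 60 epochs, five
seeds) reach a mean test F1 near 90 (see below). The command line mirrors
the same operations:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fsner.R", package = "fsner"))') \
    synth --out data/
```

with subcommands `synth`, `augment`, `sample`, `train`, `predict`,
`evaluate` and `sweep` (the augmentation-multiplier experiment).

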