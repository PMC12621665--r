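# cryoscreen

Few-shot quality screening of cryo-EM micrographs.

Micrograph screening is the first triage step of a cryo-EM processing
pipeline: exposures showing crystalline ice, contamination, stage drift or
support-film edges must be discarded before they waste downstream compute.
Conventional classifiers need hundreds of labels per imaging condition;
`cryoscreen` instead learns a metric embedding from as few as 1–5 labeled
micrographs per class and classifies the rest by nearest-neighbour voting.

## Method in brief

Each micrograph contributes four crops; every crop is paired with its
centered log-scaled power spectrum, so the model sees both real-space and
Fourier-space evidence. A dual-stream CNN (unshared weights per stream,
concatenated features, head: linear→256 → ReLU → dropout 0.5 → linear→128 →
batch norm) is trained with the triplet loss

```
L(a, p, n) = max(0, ||f(a) − f(p)||² − ||f(a) − f(n)||² + α),   α = 0.2
```

using online batch-hard mining (per anchor: farthest positive, nearest
negative within the batch) and Adam at learning rate 1e-4. Inference is
k-NN over crop embeddings against the labeled support set (k chosen on a
validation split), followed by majority voting across a micrograph's crops
with ties resolved to "bad" — the conservative choice for a screening tool.

Evaluation uses step-wise average precision with tied scores processed as a
single block, normalized by the majority-class proportion of the test set
("AUPRC Gain"). Under this convention a collapsed constant-score classifier
scores exactly 1.0, so Gain > 1 certifies genuine discrimination — the
failure mode that matters here, since unweighted cross-entropy training
collapses to the majority class in the few-shot regime.

A seeded synthetic micrograph simulator (analytic stand-ins for the four
defect kinds) makes the whole pipeline testable without external data.

## Worked example

Simulate a labeled dataset, train a 5-shot model, and evaluate it:

```r
library(cryoscreen)

cfg  <- synthetic_config(image_size = 256, n_good = 60, n_bad = 20, seed = 1)
man  <- read_manifest(generate_dataset(cfg, "demo_data"))
pp   <- preprocess_config(crop_size = 128, crops_per_micrograph = 4,
                          model_input_size = 64)

res <- run_experiment(man, model_config("tiny_cnn"),
                      train_config(max_epochs = 8, batches_per_epoch = 20),
                      inference_config(), pp,
                      shots_list = 5, seeds = c(0, 1, 2))
subset(res, level == "micrograph" & seed == "mean",
       c(n_per_class, auprc, auprc_gain, precision_good, recall_good))
```

which prints (numbers produced by this exact script):

```
  n_per_class     auprc auprc_gain precision_good recall_good
8           5 0.9271944   1.236259      0.9055556   0.7222222
```

`auprc` is the micrograph-level average precision of the mean crop
good-fraction, averaged over the three seeds; `auprc_gain = 1.24` is that
AUPRC divided by the test split's majority-good proportion (0.75 here), so
the model sits well above the collapsed-classifier baseline of 1.0. The
synthetic defects are deliberately separable (amplitude 3 x noise_sd); on
real data, gains are smaller and grow with the number of shots.

The same stages are scriptable from the shell:

```sh
Rscript inst/cli/cryoscreen simulate       --config config.json
Rscript inst/cli/cryoscreen train          --config config.json
Rscript inst/cli/cryoscreen evaluate       --config config.json
Rscript inst/cli/cryoscreen run-experiment --config config.json
```

with a single JSON config holding the `synthetic`, `preprocess`, `model`,
`train` and `inference` sections plus paths and the experiment grid. Every
run writes a `run_info.json` provenance block (config hash, seeds, package
version).

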