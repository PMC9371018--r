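# mlpimpute

Imputation of **discrete (categorical) missing data** with one multilayer
perceptron per missingness pattern, trained by momentum gradient descent on
one-hot encoded attributes after a mechanism-aware prefilling step — plus
everything needed to study such imputers: MCAR/MAR/NMAR amputation
simulators with exact per-attribute budgets, eight reference imputers, two
synthetic data generators with known dependence structure, and a repeated
stratified k-fold benchmark that scores imputation quality by downstream
classification accuracy.

It is aimed at analysts of survey-, registry- and sensor-style tables whose
attributes are category labels (where a fill must be a domain member, and
"averaging" donors is undefined) and at methodologists who need a controlled
test bed for categorical missing-data experiments.

## The method in brief

Split the table into complete rows `Dcom` and incomplete rows `Dmiss`. Each
incomplete row exhibits a *missing type* `mt` — the exact set of attribute
indices it is missing — and the distinct types partition `Dmiss`. For each
type, a fully connected network maps the one-hot blocks of the attributes
outside `mt` to the blocks inside it:

```
hidden:  a = relu(W x + b)        (three hidden layers of 32 units)
output:  y = sigmoid(W a + b)     (one unit per one-hot position)
loss:    binary cross-entropy, mean over output units
update:  v <- beta v + (1 - beta) grad ;  theta <- theta - alpha v
```

with momentum `beta = 0.9`. Before training, holes are *prefilled* (random
draws from the observed frequencies under MCAR, per-attribute mode under
MAR/NMAR) so that rows of other missing types still contribute training
inputs; training targets are always genuinely observed cells. Fills are
decoded by per-block arg-max and merged back in the original row order.

Reference imputers for comparison: mode, frequency-weighted random,
hot-deck and k-NN donors over Hamming distance on the one-hot encoding,
CART/random-forest learners (delegated to `rpart`/`randomForest`), an
autoencoder, and a plain per-type MLP (zero momentum, no prefilling) that
isolates exactly what momentum + prefilling buy.

## Worked example

```r
library(mlpimpute)

## a complete categorical table with known structure:
## 500 rows, 6 attributes of 4 categories, 4 latent classes, 10% noise
tab <- gen_latent_class(n_rows = 500, n_attrs = 6, n_classes = 4,
                        noise = 0.1, seed = 42)

## delete exactly 20% of each feature column, completely at random
amp <- ampute(tab, ampute_config("MCAR", rate = 0.2, seed = 7))
sum(missing_mask(amp))              # 600 missing cells
length(detect_missing_types(amp))   # 46 distinct missingness patterns

## impute with one momentum-trained network per pattern
cfg    <- train_config(epochs = 200, seed = 1)
filled <- impute_typed_mlp(amp, mechanism = "MCAR", config = cfg)

## how many deleted cells were restored to their true value?
fill_accuracy(tab, amp, filled)                  # 0.658
fill_accuracy(tab, amp, impute_mode(amp))        # 0.612
fill_accuracy(tab, amp, impute_mlp(amp, cfg))    # 0.628

## downstream usefulness: CART accuracy on the imputed table
repeated_kfold_accuracy(filled, learner_rpart(seed = 1),
                        k = 10, repeats = 5, seed = 3)
# $mean 0.826   $sd 0.006
```

The typed networks restore 65.8% of the deleted cells — above both the mode
baseline (61.2%, the best any dependence-blind method can do here) and the
plain per-type MLP without momentum or prefilling (62.8%). The imputed table
supports a 0.826 ± 0.006 ten-fold CART accuracy on the 4-class label.

A full grid (datasets × mechanisms × rates × imputers × classifiers, plus an
un-amputed origin control, all methods paired on identical masks) is one
call: `run_benchmark()`; `aggregate_benchmark()` averages it over rates.

## Command line

A thin wrapper over the same functions ships at `inst/cli/mlpimpute`:

```sh
mlpimpute synth     --generator latent --n 500 --seed 1 --out d.csv --schema-out s.json
mlpimpute ampute    --mechanism MAR --rate 0.2 --seed 2 --in d.csv --schema s.json --out amp.csv
mlpimpute impute    --method imlp --mechanism MAR --seed 3 --in amp.csv --schema s.json --out filled.csv
mlpimpute benchmark --config cfg.json --seed 4 --out results.csv
```

CSV follows the common `?`-sentinel convention for missing cells; the schema
JSON declares per-attribute domains, kinds and the class column.

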