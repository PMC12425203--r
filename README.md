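# ehrdx

Automated classification of clinical diagnoses from electronic health
records (EHRs), for researchers in clinical NLP and EHR phenotyping who need
a fully inspectable, deterministic implementation of the
transformer + multi-task + transfer-learning recipe — and a synthetic
clinical corpus generator to exercise it, since the corpora such models are
usually trained on are credentialed.

## What it implements

**Biased-attention text encoder.** Notes are normalized (abbreviation
expansion, synonym canonicalization), tokenized by greedy longest-match
subwords with clinical concept recognition, negation windows and temporal
flags. Attention logits carry an additive diagnostic-relevance bias from a
learned category-pair table B:

    A_k = (Q_k K_k^T + B_med) / sqrt(d_k)

and the note embedding concatenates the final [CLS] state with mean-pooled
states over concept positions:

    z = [ h_CLS^L ; (1/|C|) Σ_{c∈C} h_c^L ]

**Gated multi-task head.** z is fused with the structured metadata vector m
through elementwise sigmoid gates, passed through residual dense layers, and
decoded by per-task softmax heads. Task losses combine with importance
weights α_t = I_t / Σ_k I_k; a learned row-stochastic task-relationship
matrix R_ij = softmax_j(h^T U_ij h) weights the per-task gradients over the
shared parameters (w_t = R_tt / Σ_k R_tk).

**Transfer learning.** Bottleneck adapters h + W_down relu(W_up h) over a
frozen backbone; an adversarial domain-confusion loss with the adaptive
coefficient γ(1 − 2 D_acc) driven by a domain classifier's running accuracy;
a curriculum ramp λ(t) = λ_max min(1, t/τ) on the target-domain loss; and
teacher–student distillation KL(teacher ∥ student) + L_task.

All forward *and* backward passes are hand-derived in base R and verified
against central finite differences in the test suite; no deep-learning
framework is involved.

## Worked example

```r
library(ehrdx)

lex    <- generate_lexicon(n_concepts = 16, n_categories = 4, seed = 42)
cfg    <- synthetic_config(n_records = 300, n_tasks = 2,
                           task_correlation = 0.8, domain_shift = 0, seed = 42)
corpus <- generate_corpus(cfg, lex)

exp_cfg <- experiment_config(d_model = 16, n_layers = 1, n_heads = 2,
                             ffn_dim = 32, shared_widths = c(16, 8),
                             dropout = 0.1, epochs = 4, lr_backbone = 2e-3,
                             lr_task = 6e-3, seeds = 1, split_seed = 42)
res <- run_training(corpus, exp_cfg)
res$per_seed
#>   seed  accuracy  macro_f1 precision    recall
#> 1    1 0.8586957 0.8592415 0.8633893 0.8586957
res$history[["1"]][, c("epoch", "train_loss", "val_loss", "val_f1")]
#>   epoch train_loss  val_loss    val_f1
#> 1     1  0.2914360 0.3360619 0.8622169
#> 2     2  0.2424915 0.2996756 0.8974969
#> 3     3  0.2222183 0.2940903 0.8741532
#> 4     4  0.2219053 0.2934161 0.8741532
```

The run trains a tiny two-task model on 300 synthetic notes (70/15/15
stratified split) and reports held-out test metrics per seed plus per-epoch
train/validation curves: the model reaches ~0.86 test accuracy and macro-F1
because the generator plants concept mentions, negations and metadata
signals that the encoder is designed to pick up.

Parameter accounting for the full-scale reference backbone:

```r
count_parameters(backbone_config())
#> [1] 109482240
```

Other entry points: `run_ablation()` (BiRNN / single-task / random-init /
CNN-RNN variants on identical splits), `robustness_suite()` (clean vs noisy
vs missing vs adversarial test conditions), `temporal_split_eval()`
(train on the earliest era, evaluate per era), `adapter_retention()`,
`mtl_benefit()`, `confusion_efficacy()`, `distill_benefit()`, and a thin CLI
at `inst/cli/ehrdx` (`generate`, `preprocess`, `train`, `evaluate`,
`ablate`, `robustness`, `temporal`, `distill`).

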