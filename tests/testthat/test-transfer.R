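# Adapters, freeze plans, domain confusion, curriculum, two-phase objective,
# distillation.

test_that("adapter forward follows the printed bottleneck composition", {
  set.seed(3)
  d <- 12; r <- 4
  ad <- list(Wup = matrix(rnorm(r * d), r, d), Wdown = matrix(0, d, r))
  h <- rnorm(d)
  # zero W_down with residual: exact identity at initialization
  expect_identical(adapter_forward(h, ad, use_residual = TRUE), h)
  expect_equal(adapter_forward(h, ad, use_residual = FALSE), rep(0, d))
  # nonzero path matches a direct computation
  ad$Wdown <- matrix(rnorm(d * r), d, r)
  manual <- as.numeric(ad$Wdown %*% pmax(as.numeric(ad$Wup %*% h), 0))
  expect_equal(adapter_forward(h, ad, use_residual = FALSE), manual)
  expect_equal(adapter_forward(h, ad, use_residual = TRUE), h + manual)
  bad <- list(Wup = matrix(0, 12, 12), Wdown = matrix(0, 12, 12))
  expect_error(adapter_forward(h, bad), "rank")
  expect_error(adapter_config(rank = 0), "rank")
})

test_that("adapter parameter count is 2 d r per module", {
  expect_equal(adapter_param_count(768, 64), 98304)
  expect_equal(adapter_param_count(32, 8), 2 * 32 * 8)
})

test_that("freeze plan freezes the backbone and reports the frozen fraction", {
  setup <- tiny_model_setup(n = 10)
  model <- add_adapters(setup$model, adapter_config(rank = 4), seed = 2)
  plan <- build_freeze_plan(model)
  nms <- names(model$params)
  frozen <- nms[!plan$trainable]
  expect_true(all(grepl("^(token_embedding|bias_table|layer)", frozen)))
  expect_true(all(plan$trainable[grepl("^adapter", nms)]))
  expect_true(all(plan$trainable[grepl("^(fus|sh|rel|head)", nms)]))
  sizes <- vapply(model$params, length, numeric(1))
  expect_equal(plan$frozen_fraction, sum(sizes[frozen]) / sum(sizes))
  # no freezing: fraction 0
  expect_equal(build_freeze_plan(model, freeze_backbone = FALSE)$frozen_fraction, 0)
  # a plan that freezes everything refuses to train
  plan_all <- plan
  plan_all$trainable[] <- FALSE
  expect_error(train_model(model, setup$prep$records[1:4], plan = plan_all),
               "no trainable")
})

test_that("reference-scale freeze plan exceeds the 90 percent bound", {
  backbone <- count_parameters(backbone_config())
  trainable <- 12 * adapter_param_count(768, 64) + 5e5  # adapters + head stack
  frac <- frozen_fraction_counts(backbone, trainable)
  expect_gte(frac, 0.90)
  expect_equal(frac, 0.9848, tolerance = 1e-3)
})

test_that("domain confusion loss equals BCE with the stated closed forms", {
  # a classifier with zero weights outputs exactly 0.5 -> loss = ln 2
  D <- init_domain_classifier(4, width = 3, seed = 1)
  D$W1[] <- 0; D$b1[] <- 0; D$W2[] <- 0; D$b2 <- 0
  f <- matrix(rnorm(20), 5, 4)
  res <- domain_confusion_loss(f, c(0, 1, 0, 1, 1), D)
  expect_equal(res$loss, log(2), tolerance = 1e-12)
  expect_gte(res$loss, 0)
  # single-domain batch is skipped with a warning
  expect_warning(out <- domain_confusion_loss(f, rep(1, 5), D), "single-domain")
  expect_null(out)
  # on linearly separated features a trained probe reaches high accuracy
  set.seed(8)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  feats <- matrix(rnorm(n * 4), n, 4) + 3 * y
  D2 <- init_domain_classifier(4, width = 8, seed = 2)
  for (k in 1:200) {
    r <- domain_confusion_loss(feats, y, D2)
    D2$W1 <- D2$W1 - 0.5 * r$grad_D$W1; D2$b1 <- D2$b1 - 0.5 * r$grad_D$b1
    D2$W2 <- D2$W2 - 0.5 * r$grad_D$W2; D2$b2 <- D2$b2 - 0.5 * r$grad_D$b2
  }
  expect_gte(domain_confusion_loss(feats, y, D2)$acc, 0.95)
})

test_that("adaptive loss vanishes at D_acc = 0.5 and follows the reversal magnitude", {
  expect_identical(adaptive_total_loss(1.3, 0.9, 0.5, gamma = 2), 1.3)
  expect_identical(adaptive_total_loss(1.3, 0.9, 0.9, gamma = 0), 1.3)
  expect_equal(adaptive_total_loss(1.0, 0.7, 1.0, gamma = 1), 1.7)
  # literal printed sign flips for D_acc > 0.5
  expect_equal(adaptive_total_loss(1.0, 0.7, 1.0, gamma = 1, sign_mode = "literal"),
               1.0 - 0.7)
  expect_error(adaptive_total_loss(1, 1, 0.5, gamma = -1), "gamma")
  expect_error(adaptive_total_loss(1, 1, 1.5, gamma = 1), "D_acc")
  expect_equal(confusion_coefficient(0.5, 3), 0)
  expect_equal(confusion_coefficient(1, 3), 3)
})

test_that("curriculum schedule matches the closed form at every integer step", {
  expect_equal(curriculum_lambda(0, 0.8, 100), 0)
  expect_equal(curriculum_lambda(50, 0.8, 100), 0.4)
  expect_equal(curriculum_lambda(1000, 0.8, 100), 0.8)
  t <- 0:500
  expect_equal(curriculum_lambda(t, 0.37, 211), 0.37 * pmin(1, t / 211))
  expect_true(all(diff(curriculum_lambda(t, 1.5, 37)) >= 0))
  expect_error(curriculum_lambda(5, 1, 0), "tau")
  expect_error(curriculum_lambda(-1, 1, 10), "nonnegative")
})

test_that("two-phase objective is the stated linear combination", {
  expect_equal(two_phase_objective(0.3, 0.5, 0), 0.3)
  expect_equal(two_phase_objective(0.3, 0.5, 1), 0.8)
  lams <- seq(0, 2, by = 0.25)
  vals <- vapply(lams, function(l) two_phase_objective(0.3, 0.5, l), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(two_phase_objective(1, 1, -0.1), "lambda")
})

test_that("distillation KL has the right zero, value and sign", {
  lg <- c(1.2, -0.3, 0.8)
  same <- distill_loss(lg, lg, L_task_student = 0.4, temperature = 2)
  expect_equal(same$kl, 0, tolerance = 1e-12)
  expect_equal(same$total, 0.4, tolerance = 1e-12)
  # near-one-hot teacher vs uniform student at temperature 1: KL -> ln 2
  oh <- distill_loss(c(50, -50), c(0, 0), temperature = 1)
  expect_equal(oh$kl, log(2), tolerance = 1e-6)
  set.seed(12)
  for (i in 1:10) {
    kl <- distill_loss(rnorm(4), rnorm(4), temperature = runif(1, 0.5, 4))$kl
    expect_gte(kl, 0)
  }
  expect_error(distill_loss(c(1, 2), c(1, 2, 3)), "arity")
  expect_error(distill_loss(c(1, 2), c(1, 2), temperature = 0), "temperature")
})

test_that("frozen backbone parameters are bit-identical after adapter training", {
  setup <- tiny_model_setup(n = 24, delta = 0)
  model <- add_adapters(setup$model, adapter_config(rank = 4), seed = 3)
  plan <- build_freeze_plan(model)
  before <- model$params
  trained <- train_model(model, setup$prep$records, epochs = 2, batch_size = 8,
                         lr_backbone = 1e-3, lr_task = 5e-3, plan = plan, seed = 4)
  for (nm in names(before)) {
    if (!plan$trainable[[nm]]) {
      expect_identical(trained$params[[nm]], before[[nm]], info = nm)
    }
  }
  # and at least the adapters moved
  expect_gt(max(abs(trained$params$adapter1.Wdown - before$adapter1.Wdown)), 0)
})

test_that("distillation training never costs the student meaningful accuracy", {
  db <- distill_benefit(seeds = 1:5)
  expect_gte(db$distilled_acc, db$plain_acc - 0.02)
})

test_that("curriculum source replay and cyclical schedule run deterministically", {
  setup <- tiny_model_setup(n = 24, delta = 1)
  src <- tiny_model_setup(n = 16, delta = 0, seed = 99)
  fit <- function() {
    train_model(setup$model, setup$prep$records, epochs = 2, batch_size = 8,
                lr_backbone = 1e-3, lr_task = 3e-3, seed = 4,
                curriculum = list(lambda_max = 0.8, tau = 4),
                source_records = src$prep$records,
                cyclical = list(lr_low = 5e-4, lr_high = 2e-3))
  }
  a <- fit()
  b <- fit()
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, setup$model$params))
  expect_true(is.finite(model_loss(a, setup$prep$records)))
})
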