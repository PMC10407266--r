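test_that("encoder states have the contracted shape and are deterministic", {
  ab <- make_alphabet(c("A", "C", "D"), pad = "-")
  m <- tiny_model(ab, units = 4L, max_len = 6L)
  enc <- attn_encode(m, c("ACD", "CA"))
  expect_length(enc$states, 2)
  expect_equal(dim(enc$states[[1]]), c(6, 8))   # max_len x 2*units
  expect_equal(dim(enc$final_state), c(2, 8))
  expect_true(all(is.finite(enc$states[[1]])))

  enc2 <- attn_encode(m, c("ACD", "CA"))
  expect_identical(enc, enc2)

  expect_error(attn_encode(m, "ACQ"), "unknown symbol")
  expect_error(attn_encode(m, "ACDACDA"), "max_len")
})

test_that("attention weights are a softmax and the context is their weighted sum", {
  ab <- make_alphabet(c("A", "C", "D"), pad = "-")
  m <- tiny_model(ab, units = 4L, max_len = 6L)
  enc <- attn_encode(m, "ACDCA")
  att <- attn_attention(m, enc$final_state[1, ], enc$states[[1]])

  expect_equal(sum(att$weights), 1, tolerance = 1e-12)
  expect_true(all(att$weights >= 0))
  # brute-force weighted-sum oracle
  expect_equal(att$context,
               drop(att$weights %*% enc$states[[1]]), tolerance = 1e-12)
  # softmax of the returned scores reproduces the weights
  expect_equal(att$weights, exp(att$scores) / sum(exp(att$scores)),
               tolerance = 1e-12)

  # equal scores give uniform weights; a dominant score selects its state
  states <- matrix(rnorm(5 * 8), 5, 8)
  uniform <- attn_attention(m, rep(0, 8), states[c(1, 1, 1, 1, 1), ])
  expect_equal(uniform$weights, rep(0.2, 5), tolerance = 1e-12)
  masked <- attn_attention(m, rep(0, 8), states, mask = c(TRUE, rep(FALSE, 4)))
  expect_equal(masked$weights, c(1, 0, 0, 0, 0))
  expect_equal(masked$context, states[1, ])
})

test_that("the plain-R stage-by-stage path reproduces the compiled forward pass", {
  ab <- make_alphabet(c("A", "C", "D", "E"), pad = "-")
  m <- tiny_model(ab, units = 3L, max_len = 5L, seed = 7L)
  seqs <- c("ACDE", "EDC", "A", "CCCCC")
  idx <- attnms1:::model_indices(m, seqs)
  cpp <- attnms1:::cpp_forward(m$params, idx, details = TRUE)

  enc <- attn_encode(m, seqs)
  for (i in seq_along(seqs)) {
    expect_equal(enc$states[[i]], t(cpp$states[i, , ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    att <- attn_attention(m, enc$final_state[i, ], enc$states[[i]])
    expect_equal(att$weights, cpp$alpha[i, ], tolerance = 1e-12)
    expect_equal(att$context, cpp$context[i, ], tolerance = 1e-12)
    y <- attn_decode_scalar(m, att$context, enc$final_state[i, ])
    expect_equal(y, cpp$yhat[i], tolerance = 1e-12)
  }

  # the user-facing predict() goes through the same compiled path
  pred <- predict(m, seqs)
  expect_equal(pred$y_hat, drop(cpp$yhat), tolerance = 1e-12)
  expect_length(pred$y_hat, 4)
  expect_equal(rowSums(pred$alpha), rep(1, 4), tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  ab <- make_alphabet(c("A", "C", "D"), pad = "-")
  m <- tiny_model(ab, units = 3L, max_len = 4L, seed = 11L)
  set.seed(5)
  idx <- matrix(sample(1:4, 3 * 4, TRUE), 3, 4)
  y <- rnorm(3)
  g <- attnms1:::cpp_grad(m$params, idx, y)
  h <- 1e-6
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    take <- if (length(P) > 6) sample(length(P), 6) else seq_along(P)
    for (i in take) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (attnms1:::cpp_loss(up, idx, y) -
               attnms1:::cpp_loss(dn, idx, y)) / (2 * h)
      an <- if (nm == "bd") g[[nm]] else g[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("predictions are invariant under a consistent alphabet permutation", {
  ab1 <- make_alphabet(c("A", "C", "D", "E"), pad = "-")
  m1 <- tiny_model(ab1, units = 4L, max_len = 6L, seed = 3L)
  perm <- c(3L, 1L, 4L, 2L)            # D A E C; pad stays the last channel
  ab2 <- make_alphabet(ab1$residues[perm], pad = "-")
  m2 <- m1
  m2$alphabet <- ab2
  m2$params$Wf[seq_along(perm), ] <- m1$params$Wf[perm, ]
  m2$params$Wb[seq_along(perm), ] <- m1$params$Wb[perm, ]
  seqs <- c("ACDE", "EEDA", "CAD")
  expect_equal(predict(m2, seqs)$y_hat, predict(m1, seqs)$y_hat,
               tolerance = 1e-12)
  expect_equal(predict(m2, seqs)$alpha, predict(m1, seqs)$alpha,
               tolerance = 1e-12)
})

test_that("training descends on learnable data and fits constant targets", {
  ab <- make_alphabet(c("A", "C", "D", "E"), pad = NULL)
  set.seed(21)
  n <- 600
  contrib <- c(A = 1, C = 2, D = 3, E = 4)
  seqs <- replicate(n, paste(sample(names(contrib), 6, TRUE), collapse = ""))
  y <- vapply(seqs, function(s) sum(contrib[strsplit(s, "")[[1]]]), 0)
  ys <- (y - min(y)) / (max(y) - min(y))
  cfg <- attn_config(units = 8L, max_len = 6L, batch_size = 32L,
                     epochs = 40L, seed = 2L)
  m <- attn_train(attn_init(ab, cfg), seqs[1:500], ys[1:500],
                  seqs[501:600], ys[501:600])
  expect_lt(tail(m$history$train_mse, 1), m$history$train_mse[1])
  expect_length(m$history$val_mae, length(m$history$train_mse))
  expect_gt(cor(predict(m, seqs[501:600])$y_hat, ys[501:600]), 0.9)

  # constant targets: predictions converge toward the constant
  mc <- attn_train(attn_init(ab, cfg), seqs[1:200], rep(0.4, 200))
  expect_lt(tail(mc$history$train_mse, 1), 1e-3)
  expect_equal(mean(predict(mc, seqs[201:260])$y_hat), 0.4, tolerance = 0.05)

  expect_error(attn_train(attn_init(ab, cfg), character(0), numeric(0)),
               "empty")
  expect_error(attn_train(attn_init(ab, cfg), seqs[1:10], ys[1:5]),
               "equal length")
})

test_that("early stopping restores the best-validation weights", {
  ab <- make_alphabet(c("A", "C"), pad = NULL)
  set.seed(8)
  seqs <- replicate(300, paste(sample(c("A", "C"), 4, TRUE), collapse = ""))
  y <- runif(300)          # unlearnable noise: validation must plateau
  cfg <- attn_config(units = 4L, max_len = 4L, batch_size = 32L,
                     epochs = 30L, patience = 2L, seed = 1L)
  m <- attn_train(attn_init(ab, cfg), seqs[1:200], y[1:200],
                  seqs[201:300], y[201:300])
  expect_lt(length(m$history$train_mse), 30)
  expect_equal(m$history$best_epoch, which.min(m$history$val_mae))
})
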