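# Numerical gradient checks for the autodiff engine: every layer's analytic
# backward pass is compared against central finite differences on small
# random inputs.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x[i] + eps; x2[i] <- x[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

gradcheck <- function(layerfun, fwd, H = 5, W = 6, C = 2, tol = 1e-6) {
  x <- array(rnorm(H * W * C), c(H, W, C))
  ly <- layerfun(C)
  tape <- stomakit:::new_tape()
  nd <- fwd(tape, ly, stomakit:::new_leaf(x))
  wgt <- rnorm(length(nd$value))
  if (!is.null(dim(nd$value))) dim(wgt) <- dim(nd$value)
  loss <- function(xv) {
    tape <- stomakit:::new_tape()
    sum(fwd(tape, ly, stomakit:::new_leaf(xv))$value * wgt)
  }
  tape <- stomakit:::new_tape()
  xn <- stomakit:::new_leaf(x)
  nd <- fwd(tape, ly, xn)
  root <- stomakit:::new_node(tape, sum(nd$value * wgt),
                              backward = function(n)
                                stomakit:::acc_grad(nd, n$grad * wgt))
  stomakit:::tape_backward(tape, root)
  errs <- c(dx = max(abs(num_grad(loss, x) - xn$grad)))
  ps <- if (is.null(ly)) list() else stomakit:::collect_params(ly)
  for (p in ps) {
    lossp <- function(v) {
      old <- p$value
      dim(v) <- dim(old)
      p$value <- v
      on.exit(p$value <- old)
      loss(x)
    }
    gp <- num_grad(lossp, as.vector(p$value))
    got <- if (is.null(p$grad)) 0 * p$value else p$grad
    errs[p$name] <- max(abs(gp - as.vector(got)))
  }
  errs
}

test_that("analytic gradients match finite differences for all layer types", {
  set.seed(81)
  sk <- asNamespace("stomakit")
  cases <- list(
    conv3_s1 = list(function(C) sk$make_conv(C, 3, 3), sk$conv_fwd),
    conv3_s2 = list(function(C) sk$make_conv(C, 3, 3, stride = 2L),
                    sk$conv_fwd),
    conv1 = list(function(C) sk$make_conv(C, 3, 1, pad = 0L), sk$conv_fwd),
    conv7 = list(function(C) sk$make_conv(C, 1, 7, pad = 3L), sk$conv_fwd),
    norm = list(function(C) sk$make_norm(C),
                function(t, l, x) sk$norm_fwd(t, l, x, TRUE)),
    block = list(function(C) sk$make_block(C, 4, 2L),
                 function(t, l, x) sk$block_fwd(t, l, x, TRUE)),
    cbam = list(function(C) sk$make_cbam(C, 2),
                function(t, l, x) sk$cbam_fwd(t, l, x, TRUE)),
    deform = list(function(C) sk$make_deform_conv(C, 3), sk$deform_conv_fwd),
    up2 = list(function(C) sk$make_up(C, 3, 2),
               function(t, l, x) sk$up_fwd(t, l, x, TRUE)),
    hda2 = list(function(C) sk$make_hda(2, C, 4),
                function(t, l, x) sk$hda_tree_fwd(t, l$tree, x, TRUE)),
    softplus = list(function(C) NULL, function(t, l, x) sk$softplus_fwd(t, x)),
    chanpool = list(function(C) NULL, function(t, l, x) sk$chan_pool_fwd(t, x))
  )
  for (nm in names(cases)) {
    errs <- gradcheck(cases[[nm]][[1]], cases[[nm]][[2]],
                      H = if (nm %in% c("block", "hda2")) 6 else 5,
                      W = 6, C = 2)
    expect_lt(max(errs), 1e-6, label = paste0(nm, ": ", max(errs)))
  }
})

test_that("loss gradients match finite differences", {
  set.seed(82)
  sk <- asNamespace("stomakit")
  q <- matrix(0, 4, 4); q[2, 3] <- 1; q[1, 1] <- 0.6
  p <- array(runif(16, 0.05, 0.95), c(4, 4, 1))
  f <- function(pv) {
    dim(pv) <- c(4, 4, 1)
    sk$focal_loss_fwd(sk$new_tape(), sk$new_leaf(pv), q, 2, 4)$value
  }
  tape <- sk$new_tape(); pn <- sk$new_leaf(p)
  nd <- sk$focal_loss_fwd(tape, pn, q, 2, 4)
  sk$tape_backward(tape, nd)
  expect_lt(max(abs(num_grad(f, p) - pn$grad)), 1e-6)

  sz <- matrix(c(15, 12, 18, 5, 4, 6), 3, 2)
  trueG <- c(1.2, 1.5, 0.9)
  f4 <- function(v) {
    dim(v) <- c(3, 2)
    sk$cond_loss_fwd(sk$new_tape(), sk$new_leaf(v), trueG, 50, 0.625, 4,
                     conductance_params())$value
  }
  tape <- sk$new_tape(); pn <- sk$new_leaf(sz)
  nd <- sk$cond_loss_fwd(tape, pn, trueG, 50, 0.625, 4, conductance_params())
  sk$tape_backward(tape, nd)
  expect_lt(max(abs(num_grad(f4, as.vector(sz)) - as.vector(pn$grad))), 1e-6)

  av <- c(10, 170, 85); at <- c(30, 5, 100)
  f3 <- function(v)
    sk$angle_loss_fwd(sk$new_tape(), sk$new_leaf(v), at, TRUE)$value
  tape <- sk$new_tape(); pn <- sk$new_leaf(av)
  nd <- sk$angle_loss_fwd(tape, pn, at, TRUE)
  sk$tape_backward(tape, nd)
  expect_lt(max(abs(num_grad(f3, av) - pn$grad)), 1e-6)
})

test_that("AdamW decays weights and minimizes a quadratic", {
  set.seed(83)
  sk <- asNamespace("stomakit")
  p <- sk$new_param(c(5, -3))
  st <- sk$adamw_state(list(p))
  for (t in 1:400) {
    p$grad <- 2 * (p$value - c(1, 2))
    st <- sk$adamw_step(list(p), st, lr = 0.05, weight_decay = 0, t = t)
  }
  expect_equal(p$value, c(1, 2), tolerance = 1e-2)
  # pure weight decay shrinks parameters toward zero
  p2 <- sk$new_param(c(4))
  st2 <- sk$adamw_state(list(p2))
  for (t in 1:50) {
    p2$grad <- 0
    st2 <- sk$adamw_step(list(p2), st2, lr = 0.1, weight_decay = 0.1, t = t)
  }
  expect_lt(abs(p2$value), 4 * (1 - 0.01)^49)
})
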