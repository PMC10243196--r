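#' @title Reverse-mode autodifferentiation tape
#'
#' @description
#' A minimal define-by-run autodiff engine. Every differentiable quantity is a
#' node (an environment holding `$v`, the value, and `$g`, the accumulated
#' gradient). Operations executed with a tape record a backward closure; calling
#' [ag_backward()] replays the records in reverse and accumulates gradients
#' into every reachable node, including the trainable parameters created with
#' [ag_param()]. Operations are coarse-grained (a whole convolution is one
#' record), so tape overhead per training step is negligible next to the
#' compiled kernels.
#'
#' @name autograd
#' @keywords internal
NULL

#' Create a new gradient tape
#' @return an environment collecting operation records
#' @keywords internal
ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$recs <- vector("list", 256L)
  t$n <- 0L
  t
}

#' Create a value node
#' @keywords internal
ag_node <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  class(nd) <- "ag_node"
  nd
}

#' Create a trainable parameter node
#' @param value initial numeric array
#' @keywords internal
ag_param <- function(value) {
  nd <- ag_node(value)
  class(nd) <- c("ag_param", "ag_node")
  nd
}

is_node <- function(x) inherits(x, "ag_node")

#' Extract the value of a node (identity on plain arrays)
#' @keywords internal
ag_val <- function(x) if (is_node(x)) x$v else x

ag_push <- function(tape, out, inputs, bwd) {
  n <- tape$n + 1L
  if (n > length(tape$recs)) tape$recs <- c(tape$recs, vector("list", length(tape$recs)))
  tape$recs[[n]] <- list(out = out, inputs = inputs, bwd = bwd)
  tape$n <- n
  invisible(out)
}

#' Run backpropagation from a scalar loss node
#'
#' @param tape the tape the loss was computed on
#' @param loss scalar output node
#' @keywords internal
ag_backward <- function(tape, loss) {
  if (!is_node(loss)) stop("loss must be an ag_node")
  loss$g <- 1
  for (i in seq.int(tape$n, 1L)) {
    r <- tape$recs[[i]]
    og <- r$out$g
    if (is.null(og)) next
    gs <- r$bwd(og)
    inputs <- r$inputs
    for (j in seq_along(inputs)) {
      inp <- inputs[[j]]
      if (is_node(inp) && !is.null(gs[[j]])) {
        inp$g <- if (is.null(inp$g)) gs[[j]] else inp$g + gs[[j]]
      }
    }
    if (!inherits(r$out, "ag_param")) r$out$g <- NULL
  }
  invisible(NULL)
}

# -- generic op helper --------------------------------------------------------
# forward always runs; the backward closure is recorded only when a tape is
# supplied AND at least one input is a node (otherwise nothing upstream needs
# a gradient).
ag_op <- function(tape, inputs, value, bwd) {
  out <- ag_node(value)
  if (!is.null(tape) && any(vapply(inputs, is_node, logical(1)))) {
    ag_push(tape, out, inputs, bwd)
  }
  out
}

# -- elementwise ops ----------------------------------------------------------

ag_add <- function(tape, a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(tape, list(a, b), av + bv, function(g) list(g, g))
}

ag_sub <- function(tape, a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(tape, list(a, b), av - bv, function(g) list(g, -g))
}

ag_mul <- function(tape, a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(tape, list(a, b), av * bv, function(g) list(g * bv, g * av))
}

ag_div <- function(tape, a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(tape, list(a, b), av / bv,
        function(g) list(g / bv, -g * av / (bv * bv)))
}

# y = a * x + b with scalar constants a, b
ag_affine <- function(tape, x, a, b) {
  xv <- ag_val(x)
  ag_op(tape, list(x), a * xv + b, function(g) list(a * g))
}

ag_square <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), xv * xv, function(g) list(2 * xv * g))
}

ag_abs <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), abs(xv), function(g) list(g * sign(xv)))
}

ag_relu <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), pmax(xv, 0), function(g) list(g * (xv > 0)))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-ag_val(x)))
  ag_op(tape, list(x), s, function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(tape, x) {
  tv <- tanh(ag_val(x))
  ag_op(tape, list(x), tv, function(g) list(g * (1 - tv * tv)))
}

# -- reductions ---------------------------------------------------------------

ag_mean <- function(tape, x) {
  xv <- ag_val(x)
  n <- length(xv)
  ag_op(tape, list(x), mean(xv),
        function(g) list(array(g / n, dim = dim(xv) %||% length(xv))))
}

ag_sum <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), sum(xv),
        function(g) list(array(g, dim = dim(xv) %||% length(xv))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- structural ops on (H, W, C, N) arrays ------------------------------------

#' Per-channel scaling (the learnable skip alpha): `y[,,c,] = x[,,c,] * a[c]`
#' @keywords internal
ag_scale_channels <- function(tape, x, a) {
  xv <- ag_val(x); av <- ag_val(a)
  d <- dim(xv)
  stopifnot(length(av) == d[3])
  aexp <- rep(rep(av, each = d[1] * d[2]), times = d[4])
  out <- xv * aexp
  dim(out) <- d
  ag_op(tape, list(x, a), out, function(g) {
    ga <- colSums(matrix(g * xv, nrow = d[1] * d[2], ncol = d[3] * d[4]))
    ga <- rowSums(matrix(ga, nrow = d[3], ncol = d[4]))
    gx <- g * aexp
    dim(gx) <- d
    list(gx, ga)
  })
}

#' Channel concatenation of a list of (H, W, C_i, N) nodes
#' @keywords internal
ag_concat_ch <- function(tape, xs) {
  vs <- lapply(xs, ag_val)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  ends <- cumsum(cs)
  starts <- ends - cs + 1
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  for (i in seq_along(vs)) out[, , starts[i]:ends[i], ] <- vs[[i]]
  ag_op(tape, xs, out, function(g) {
    lapply(seq_along(vs), function(i) {
      gi <- g[, , starts[i]:ends[i], , drop = FALSE]
      dim(gi) <- dim(vs[[i]])
      gi
    })
  })
}

#' Pixelshuffle: (H, W, r^2*C, N) -> (rH, rW, C, N), r = 2.
#'
#' Input channel k (0-based) maps to sub-position (dy, dx) = (k %/% 2 %% 2,
#' k %% 2) of output channel k %/% 4, i.e. the dx index varies fastest.
#' A pure permutation: the inverse permutation is its exact adjoint.
#' @keywords internal
ag_pixel_shuffle <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), pixel_shuffle_(xv),
        function(g) list(pixel_unshuffle_(g)))
}

#' Space-to-depth inverse of [ag_pixel_shuffle]
#' @keywords internal
ag_pixel_unshuffle <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), pixel_unshuffle_(xv),
        function(g) list(pixel_shuffle_(g)))
}

pixel_shuffle_ <- function(x) {
  d <- dim(x)  # (H, W, 4C, N)
  stopifnot(d[3] %% 4 == 0)
  Cc <- d[3] %/% 4
  dim(x) <- c(d[1], d[2], 2L, 2L, Cc, d[4])  # (H, W, dx, dy, C, N)
  x <- aperm(x, c(4L, 1L, 3L, 2L, 5L, 6L))   # (dy, H, dx, W, C, N)
  dim(x) <- c(2L * d[1], 2L * d[2], Cc, d[4])
  x
}

pixel_unshuffle_ <- function(y) {
  d <- dim(y)  # (2H, 2W, C, N)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  H <- d[1] %/% 2; W <- d[2] %/% 2
  dim(y) <- c(2L, H, 2L, W, d[3], d[4])      # (dy, H, dx, W, C, N)
  y <- aperm(y, c(2L, 4L, 3L, 1L, 5L, 6L))   # (H, W, dx, dy, C, N)
  dim(y) <- c(H, W, 4L * d[3], d[4])
  y
}

#' Channel softmax: normalizes over dim 3 of (H, W, Cls, N)
#' @keywords internal
ag_softmax_ch <- function(tape, x) {
  xv <- ag_val(x)
  d <- dim(xv)
  m <- matrix(aperm(xv, c(3, 1, 2, 4)), nrow = d[3])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  p <- sweep(m, 2, colSums(m), "/")
  pv <- aperm(array(p, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  dim(pv) <- d
  ag_op(tape, list(x), pv, function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = d[3])
    pm <- matrix(aperm(pv, c(3, 1, 2, 4)), nrow = d[3])
    gx <- pm * sweep(gm, 2, colSums(gm * pm))
    gx <- aperm(array(gx, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
    dim(gx) <- d
    list(gx)
  })
}
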