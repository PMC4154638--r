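# condition helpers: every user-facing failure carries a condition class
abort_invalid <- function(msg) {
  rlang::abort(msg, class = "psnpaths_invalid_argument")
}
abort_format <- function(msg) {
  rlang::abort(msg, class = "psnpaths_format_error")
}
abort_selection <- function(msg) {
  rlang::abort(msg, class = "psnpaths_selection_error")
}
abort_normalization <- function(msg) {
  rlang::abort(msg, class = "psnpaths_normalization_error")
}
abort_no_transition <- function(msg) {
  rlang::abort(msg, class = "psnpaths_no_transition")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# least-squares (Kabsch) superposition of `mobile` (n x 3) onto `target`
# (n x 3); returns the transformed coordinates
kabsch_fit <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a %*% t(rot), 2, ct, "+")
}
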