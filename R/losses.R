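# Classification losses with analytic gradients.

#' Softmax cross-entropy loss
#'
#' @param scores numeric score vector (one per class).
#' @param label 0-based true class index.
#' @return `list(loss, grad)` with `grad = p - onehot(label)`, `p` the
#'   softmax probabilities.
#' @export
softmax_loss <- function(scores, label) {
  k <- length(scores)
  lab <- as.integer(label) + 1L
  if (lab < 1L || lab > k) stop("label out of range", call. = FALSE)
  m <- max(scores)
  ex <- exp(scores - m)
  p <- ex / sum(ex)
  grad <- p
  grad[lab] <- grad[lab] - 1
  list(loss = -log(p[lab]), grad = grad)
}

#' One-versus-all hinge loss
#'
#' Linear hinge with targets +1 for the true class and -1 for all others:
#' `max(0, 1 - s_y) + sum_{c != y} max(0, 1 + s_c)`.
#'
#' @param scores numeric score vector.
#' @param label 0-based true class index.
#' @return `list(loss, grad)` (a subgradient at the hinge points).
#' @export
hinge_loss_ova <- function(scores, label) {
  k <- length(scores)
  lab <- as.integer(label) + 1L
  if (lab < 1L || lab > k) stop("label out of range", call. = FALSE)
  target <- rep(-1, k)
  target[lab] <- 1
  margin <- 1 - target * scores
  active <- margin > 0
  list(loss = sum(margin[active]),
       grad = ifelse(active, -target, 0))
}

loss_fn <- function(name) {
  switch(name, softmax = softmax_loss, hinge_ova = hinge_loss_ova,
         stop("unknown loss: ", name, call. = FALSE))
}
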