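FIXTURE_KINDS <- c("disorder-rich", "order-rich", "acidic", "basic", "mixed")

#' Generate synthetic protein sequences with biased composition
#'
#' Draws reproducible random sequences whose residue composition mimics
#' a sequence class of interest, so every analysis in the package can be
#' exercised offline:
#' \describe{
#'   \item{disorder-rich}{80% of sampling mass on the disorder-promoting
#'     set (P, E, S, Q, K, A, G), 20% uniform over the rest.}
#'   \item{order-rich}{80% on the order-promoting set (M, N, V, H, L, F,
#'     Y, I, W, C), 20% uniform over the rest.}
#'   \item{acidic}{60% on D/E, 40% uniform over the remaining residues
#'     excluding K, R and H — so the net charge at pH 7 is negative by
#'     construction.}
#'   \item{basic}{60% on K/R, 40% uniform excluding D and E.}
#'   \item{mixed}{uniform over the 20 standard residues.}
#' }
#' The same `(kind, length, seed)` always yields the same sequence, and
#' the global RNG state is left untouched.
#'
#' @param kind One of `r paste0('\x60"', FIXTURE_KINDS, '"\x60', collapse = ", ")`.
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A one-row tibble (`id`, `seq`, `length`); the id encodes kind,
#'   length and seed.
#' @examples
#' generate_fixture("acidic", 50, seed = 1)
#' @export
generate_fixture <- function(kind = FIXTURE_KINDS, length, seed = 1L) {
  kind <- arg_match(kind)
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != as.integer(length)) {
    abort("`length` must be a positive integer.")
  }
  w <- fixture_weights(kind)
  seq <- withr::with_seed(seed, {
    paste(sample(names(w), size = length, replace = TRUE, prob = w), collapse = "")
  })
  parse_sequence(seq, id = sprintf("%s_%d_s%d", kind, as.integer(length), as.integer(seed)))
}

fixture_weights <- function(kind) {
  scheme <- tendency_scheme()
  disorder <- scheme$residue[scheme$class == "disorder-promoting"]
  order <- scheme$residue[scheme$class == "order-promoting"]
  biased <- function(target, mass, exclude = character()) {
    pool <- setdiff(AA_STANDARD, exclude)
    rest <- setdiff(pool, target)
    w <- c(setNames(rep(mass / length(target), length(target)), target),
           setNames(rep((1 - mass) / length(rest), length(rest)), rest))
    w[pool]
  }
  switch(kind,
    "disorder-rich" = biased(disorder, 0.8),
    "order-rich" = biased(order, 0.8),
    "acidic" = biased(c("D", "E"), 0.6, exclude = c("K", "R", "H")),
    "basic" = biased(c("K", "R"), 0.6, exclude = c("D", "E")),
    "mixed" = setNames(rep(1 / 20, 20), AA_STANDARD)
  )
}
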