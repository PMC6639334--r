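#' Allowed probability and amount grids of the task design
#'
#' The task draws outcome probabilities from a four-point grid and token
#' amounts from the non-zero integers in \[-3, 3\]. Every lottery pays
#' `x_tokens` with probability `p` and 0 tokens otherwise.
#'
#' @format Numeric vectors.
#' @name design_grids
NULL

#' @rdname design_grids
#' @export
prob_grid <- c(0.25, 0.50, 0.75, 1.00)

#' @rdname design_grids
#' @export
amount_grid <- c(-3L, -2L, -1L, 1L, 2L, 3L)

#' Construct a two-outcome token lottery
#'
#' A lottery pays `x_tokens` (a non-zero integer in \[-3, 3\]) with
#' probability `p` (on the grid 0.25/0.50/0.75/1.00) and 0 tokens with
#' probability `1 - p`.
#'
#' @param x_tokens Integer token amount, one of -3, -2, -1, 1, 2, 3.
#' @param p Probability of `x_tokens`, one of 0.25, 0.50, 0.75, 1.00.
#' @return An object of class `"lottery"` with fields `x` and `p`.
#' @examples
#' lottery(2, 0.5)
#' @export
lottery <- function(x_tokens, p) {
  if (length(x_tokens) != 1L || length(p) != 1L) {
    stop("'x_tokens' and 'p' must be scalars", call. = FALSE)
  }
  if (!is.numeric(x_tokens) || is.na(x_tokens) ||
      !(x_tokens %in% amount_grid)) {
    stop("'x_tokens' must be a non-zero integer in [-3, 3]", call. = FALSE)
  }
  if (!is.numeric(p) || is.na(p) || !any(abs(p - prob_grid) < 1e-12)) {
    stop("'p' must be one of 0.25, 0.50, 0.75, 1.00", call. = FALSE)
  }
  structure(list(x = as.integer(x_tokens), p = as.numeric(p)),
            class = "lottery")
}

#' @export
print.lottery <- function(x, ...) {
  cat(sprintf("Lottery: %+d token%s with p = %.2f (0 otherwise)\n",
              x$x, if (abs(x$x) > 1L) "s" else "", x$p))
  invisible(x)
}

#' Expected value of a lottery, in tokens
#'
#' @param L A [lottery()].
#' @return `p * x_tokens`, in tokens.
#' @examples
#' expected_value(lottery(2, 0.5)) # 1 token
#' @export
expected_value <- function(L) {
  stopifnot(inherits(L, "lottery"))
  L$p * L$x
}

## Canonical pair-type test, applied to an ORDERED pair (x1,p1) vs (x2,p2).
## Canonical ordering puts the dominant member first (types 1-5) and the
## riskier member first (types 6/7). Vectorised over equal-length inputs.
.pair_type_canonical <- function(x1, p1, x2, p2) {
  type <- rep(NA_integer_, length(x1))
  eqp <- abs(p1 - p2) < 1e-12
  type[eqp & x1 > 0 & x2 < 0] <- 1L
  type[eqp & x1 > x2 & x2 > 0] <- 2L
  type[eqp & x1 > x2 & x1 < 0] <- 3L
  eqx <- x1 == x2
  type[eqx & x1 > 0 & p1 > p2] <- 4L
  type[eqx & x1 < 0 & p1 < p2] <- 5L
  type[x1 > 0 & x2 > 0 & p1 < p2 & x1 > x2] <- 6L
  type[x1 < 0 & x2 < 0 & p1 < p2 & x1 < x2] <- 7L
  type
}

## Would the canonical ordering keep (a) first, or swap to (b) first?
## Returns TRUE when the ordered pair (a, b) is already canonical for some
## type, FALSE when (b, a) is, NA when neither ordering fits any type.
.is_canonical_order <- function(xa, pa, xb, pb) {
  fwd <- .pair_type_canonical(xa, pa, xb, pb)
  rev <- .pair_type_canonical(xb, pb, xa, pa)
  ifelse(!is.na(fwd), TRUE, ifelse(!is.na(rev), FALSE, NA))
}

#' Classify an ordered pair of lotteries into the task's 7 pair types
#'
#' The seven types partition the design: types 1-5 contain a first-order
#' stochastically dominant member (mixed-sign equal-probability pairs, and
#' same-domain pairs differing in only one attribute), while types 6 (gains)
#' and 7 (losses) oppose a riskier member (larger |x|, smaller p) to a safer
#' one with no dominance. Classification first canonicalizes the order
#' (dominant or riskier member first), then tests the type-defining
#' inequalities.
#'
#' @param L1,L2 Two [lottery()] objects.
#' @return An integer in 1..7, or the character string `"unclassified"` when
#'   no type applies (e.g. identical lotteries, or mixed-sign pairs with
#'   unequal probabilities).
#' @examples
#' classify_pair(lottery(2, 0.5), lottery(-2, 0.5))   # 1
#' classify_pair(lottery(3, 0.25), lottery(1, 0.75))  # 6
#' @export
classify_pair <- function(L1, L2) {
  stopifnot(inherits(L1, "lottery"), inherits(L2, "lottery"))
  t1 <- .pair_type_canonical(L1$x, L1$p, L2$x, L2$p)
  if (!is.na(t1)) return(t1)
  t2 <- .pair_type_canonical(L2$x, L2$p, L1$x, L1$p)
  if (!is.na(t2)) return(t2)
  "unclassified"
}

#' Construct a classified, canonically ordered lottery pair
#'
#' Orders the two lotteries canonically (dominant member first for types
#' 1-5, riskier member first for types 6/7), classifies the pair, and
#' records which of the original arguments ended up first.
#'
#' @param L1,L2 Two [lottery()] objects forming a classifiable pair.
#' @return An object of class `"lottery_pair"`: a list with fields `x1`,
#'   `p1`, `x2`, `p2`, `pair_type`, and `riskier` (1 when the first,
#'   canonical member is the riskier one, i.e. for types 6/7; `NA`
#'   otherwise).
#' @examples
#' lottery_pair(lottery(1, 0.75), lottery(3, 0.25)) # canonicalized, type 6
#' @export
lottery_pair <- function(L1, L2) {
  type <- classify_pair(L1, L2)
  if (identical(type, "unclassified")) {
    stop("lottery pair fits none of the 7 design types", call. = FALSE)
  }
  if (is.na(.pair_type_canonical(L1$x, L1$p, L2$x, L2$p))) {
    tmp <- L1; L1 <- L2; L2 <- tmp
  }
  structure(list(x1 = L1$x, p1 = L1$p, x2 = L2$x, p2 = L2$p,
                 pair_type = type,
                 riskier = if (type %in% 6:7) 1L else NA_integer_),
            class = "lottery_pair")
}

#' @export
print.lottery_pair <- function(x, ...) {
  role <- if (x$pair_type %in% 6:7) "riskier" else "dominant"
  cat(sprintf("Lottery pair, type %d (L1 is the %s member)\n",
              x$pair_type, role))
  cat(sprintf("  L1: %+d tokens, p = %.2f\n", x$x1, x$p1))
  cat(sprintf("  L2: %+d tokens, p = %.2f\n", x$x2, x$p2))
  invisible(x)
}

#' Expected-value difference of a risky pair, in tokens
#'
#' For a type-6 or type-7 pair, the signed difference
#' `EV(riskier) - EV(safer)`; positive values favour the riskier option.
#'
#' @param pair A [lottery_pair()] of type 6 or 7.
#' @return The expected-value difference in tokens.
#' @examples
#' ev_difference(lottery_pair(lottery(3, 0.25), lottery(2, 0.5))) # -0.25
#' @export
ev_difference <- function(pair) {
  stopifnot(inherits(pair, "lottery_pair"))
  if (!pair$pair_type %in% 6:7) {
    stop("expected-value difference requires a riskier member (types 6/7)",
         call. = FALSE)
  }
  pair$p1 * pair$x1 - pair$p2 * pair$x2
}

#' Enumerate all lottery pairs of one design type
#'
#' Full factorial enumeration of unordered pairs over the probability grid
#' \{0.25, 0.5, 0.75, 1\} and amounts in the non-zero integers of
#' \[-3, 3\], returned in canonical order (dominant or riskier member as
#' `(x1, p1)`). Note that for type 4 the factorial grid contains 18 pairs
#' while the published design reports 12; see [design_table()].
#'
#' @param pair_type An integer in 1..7.
#' @return A data frame with columns `type`, `x1`, `p1`, `x2`, `p2`, one row
#'   per pair, ordered deterministically.
#' @examples
#' nrow(enumerate_pairs(1)) # 36
#' nrow(enumerate_pairs(6)) # 18
#' @export
enumerate_pairs <- function(pair_type) {
  if (length(pair_type) != 1L || !pair_type %in% 1:7) {
    stop("'pair_type' must be a single integer in 1..7", call. = FALSE)
  }
  g <- expand.grid(x1 = amount_grid, p1 = prob_grid,
                   x2 = amount_grid, p2 = prob_grid,
                   KEEP.OUT.ATTRS = FALSE)
  keep <- .pair_type_canonical(g$x1, g$p1, g$x2, g$p2) == pair_type
  keep[is.na(keep)] <- FALSE
  out <- g[keep, , drop = FALSE]
  out <- data.frame(type = as.integer(pair_type),
                    x1 = as.integer(out$x1), p1 = out$p1,
                    x2 = as.integer(out$x2), p2 = out$p2)
  out <- out[order(out$x1, out$p1, out$x2, out$p2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The full lottery-pair design table
#'
#' Enumerates the requested pair types and stacks them into a single design
#' table with per-type counts. The factorial grid yields 36, 12, 12, 18,
#' 18, 18, 18 pairs for types 1-7; the published design reports 12 pairs
#' for type 4, a discrepancy the table records in its `"note"` attribute
#' rather than silently subsetting.
#'
#' @param types Integer vector of pair types to include (default all 7).
#' @return A data frame of class `"design_table"` with columns `type`,
#'   `x1`, `p1`, `x2`, `p2`; attributes `counts` (named per-type counts)
#'   and `note`.
#' @examples
#' attr(design_table(), "counts")
#' @export
design_table <- function(types = 1:7) {
  if (!all(types %in% 1:7)) stop("'types' must lie in 1..7", call. = FALSE)
  tabs <- lapply(types, enumerate_pairs)
  out <- do.call(rbind, tabs)
  counts <- vapply(tabs, nrow, integer(1))
  names(counts) <- as.character(types)
  attr(out, "counts") <- counts
  attr(out, "note") <- paste(
    "Type 4 factorial enumeration yields 18 pairs;",
    "the published design reports 12 (subset not recoverable).")
  class(out) <- c("design_table", "data.frame")
  out
}

#' @export
print.design_table <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Lottery-pair design table:", nrow(x), "pairs\n")
  cat("  per-type counts:",
      paste(sprintf("T%s=%d", names(counts), counts), collapse = ", "), "\n")
  if (any(names(counts) == "4")) cat("  note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Write / read a design table as delimited text
#'
#' @param design A [design_table()] (or compatible data frame).
#' @param path File path.
#' @return `read_design` returns a plain data frame with columns `type`,
#'   `x1`, `p1`, `x2`, `p2`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[, c("type", "x1", "p1", "x2", "p2")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- utils::read.csv(path)
  need <- c("type", "x1", "p1", "x2", "p2")
  if (!all(need %in% names(out))) {
    stop("design file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out[, need]
}
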