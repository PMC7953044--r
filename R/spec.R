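#' Define a confirmatory factor model structure
#'
#' A `cfa_spec` records which items load on which factors, with each item
#' assigned to exactly one factor and the latent scale set by a unit loading
#' identification (ULI) constraint: the loading of one reference item per
#' factor (by default the first item listed) is fixed to 1 and the factor
#' variances are free.
#'
#' @param factors Named list; each element is a character vector of item
#'   names belonging to that factor.  An empty list specifies the
#'   independence model (no factors; free means and variances only), used as
#'   the baseline for the comparative fit index.
#' @param item_names Character vector giving the item (column) order of the
#'   data the spec will be applied to.  Every item must appear in exactly one
#'   factor unless `factors` is empty.
#' @param reference_items Optional named character vector, one entry per
#'   factor, naming the item whose loading is fixed to 1.  Defaults to the
#'   first item listed for each factor.
#' @return An object of class `cfa_spec`.
#' @seealso [mspss_spec()] for the canonical 12-item MSPSS structures.
#' @examples
#' cfa_spec(list(F1 = c("q1", "q2"), F2 = c("q3", "q4")),
#'          item_names = paste0("q", 1:4))
#' @export
cfa_spec <- function(factors, item_names, reference_items = NULL) {
  stopifnot(is.character(item_names), length(item_names) >= 1,
            !anyDuplicated(item_names))
  p <- length(item_names)
  m <- length(factors)
  if (m > 0 && (is.null(names(factors)) || any(names(factors) == "")))
    stop("'factors' must be a named list")
  factor_of <- integer(p)
  if (m > 0) {
    all_items <- unlist(factors, use.names = FALSE)
    if (anyDuplicated(all_items))
      stop("each item may load on exactly one factor")
    missing_items <- setdiff(item_names, all_items)
    if (length(missing_items))
      stop("items not assigned to any factor: ",
           paste(missing_items, collapse = ", "))
    unknown <- setdiff(all_items, item_names)
    if (length(unknown))
      stop("unknown items in 'factors': ", paste(unknown, collapse = ", "))
    for (k in seq_len(m)) factor_of[match(factors[[k]], item_names)] <- k
    if (is.null(reference_items))
      reference_items <- vapply(factors, `[`, character(1), 1)
    if (length(reference_items) != m ||
        !all(mapply(`%in%`, reference_items, factors)))
      stop("'reference_items' must name one item within each factor")
    names(reference_items) <- names(factors)
  } else {
    reference_items <- character(0)
  }
  is_ref <- item_names %in% reference_items
  structure(
    list(p = p, m = m,
         item_names = item_names,
         factor_names = names(factors),
         factors = factors,
         factor_of = factor_of,
         is_ref = is_ref,
         reference_items = reference_items),
    class = "cfa_spec")
}

#' @export
print.cfa_spec <- function(x, ...) {
  if (x$m == 0) {
    cat("CFA model spec: independence model (", x$p, " items, no factors)\n",
        sep = "")
  } else {
    cat("CFA model spec: ", x$m, " factor(s), ", x$p, " items\n", sep = "")
    for (k in seq_len(x$m)) {
      its <- x$factors[[k]]
      ref <- x$reference_items[k]
      cat("  ", x$factor_names[k], ": ",
          paste(ifelse(its == ref, paste0(its, "*"), its), collapse = ", "),
          "\n", sep = "")
    }
    cat("  (* reference item, loading fixed to 1)\n")
  }
  invisible(x)
}

#' Canonical MSPSS factorial structures
#'
#' Builds the factor structures considered when validating the 12-item
#' Multidimensional Scale of Perceived Social Support: items 1-4 form the
#' Significant Other (SO) subscale, items 5-8 Family (FA), and items 9-12
#' Friends (FR).  Besides the theoretical three-factor model, a one-factor
#' model and the three possible two-factor collapses are available, in the
#' order they are conventionally evaluated (most parsimonious first).
#'
#' @param structure One of `"one"`, `"two_so_fr"` (SO and FR combined),
#'   `"two_fa_fr"`, `"two_fa_so"`, `"three"`, or `"independence"`.
#' @param item_names Item names in column order; default `q1`...`q12`.
#' @return A [cfa_spec()] object.
#' @examples
#' mspss_spec("three")
#' @export
mspss_spec <- function(structure = c("three", "one", "two_so_fr",
                                     "two_fa_fr", "two_fa_so",
                                     "independence"),
                       item_names = paste0("q", 1:12)) {
  structure <- match.arg(structure)
  stopifnot(length(item_names) == 12)
  so <- item_names[1:4]; fa <- item_names[5:8]; fr <- item_names[9:12]
  factors <- switch(structure,
    three        = list(SO = so, FA = fa, FR = fr),
    one          = list(G = c(so, fa, fr)),
    two_so_fr    = list(SOFR = c(so, fr), FA = fa),
    two_fa_fr    = list(SO = so, FAFR = c(fa, fr)),
    two_fa_so    = list(FASO = c(so, fa), FR = fr),
    independence = list())
  cfa_spec(factors, item_names)
}

#' Names of the MSPSS model sequence
#'
#' The evaluation order used in the validation workflow: one-factor first
#' (most parsimonious), then the three two-factor collapses, then the
#' theoretical three-factor structure.
#' @return Character vector of structure labels accepted by [mspss_spec()].
#' @export
mspss_model_sequence <- function() {
  c("one", "two_so_fr", "two_fa_fr", "two_fa_so", "three")
}

# Number of free parameters of a spec (intercepts + free loadings +
# residual variances + factor SDs + correlations).
n_free_parameters <- function(spec) {
  spec$p + (if (spec$m > 0) spec$p - spec$m else 0) + spec$p + spec$m +
    if (spec$m > 1) spec$m * (spec$m - 1) / 2 else 0
}
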