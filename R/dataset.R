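#' Binary SLE liquidus dataset
#'
#' A container for liquidus observations of a binary system: a data frame of
#' points `(x1, T_K, branch)` where `x1` is the liquid mole fraction of
#' Component 1 (the high-melting component by convention), `T_K` the liquidus
#' temperature in K, and `branch` indicates which solid crystallizes (1 or 2).
#'
#' @param points data frame with numeric columns `x1`, `T_K` and integer
#'   column `branch` (values 1 or 2).
#' @param name1,name2 component labels.
#' @param provenance free-text note on where the data came from (literature
#'   citation, generator settings, ...).
#' @return An object of class `"sle_dataset"`: the validated data frame with
#'   attributes `name1`, `name2`, `provenance`.
#' @export
sle_dataset <- function(points, name1 = "Component 1", name2 = "Component 2",
                        provenance = "") {
  if (!is.data.frame(points) || !all(c("x1", "T_K", "branch") %in% names(points)))
    stop_parse("`points` must be a data frame with columns x1, T_K, branch")
  x1 <- as.numeric(points$x1)
  T_K <- as.numeric(points$T_K)
  branch <- as.integer(points$branch)
  bad <- which(!is.finite(x1) | x1 < 0 | x1 > 1)
  if (length(bad))
    stop_parse(sprintf("x1 outside [0, 1] at row(s): %s",
                       paste(bad, collapse = ", ")))
  bad <- which(!is.finite(T_K) | T_K <= 0)
  if (length(bad))
    stop_parse(sprintf("non-positive temperature at row(s): %s",
                       paste(bad, collapse = ", ")))
  bad <- which(!branch %in% c(1L, 2L))
  if (length(bad))
    stop_parse(sprintf("branch must be 1 or 2 at row(s): %s",
                       paste(bad, collapse = ", ")))
  out <- data.frame(x1 = x1, T_K = T_K, branch = branch)
  structure(out, class = c("sle_dataset", "data.frame"),
            name1 = name1, name2 = name2, provenance = provenance)
}

#' @export
print.sle_dataset <- function(x, ...) {
  cat(sprintf("SLE dataset: %s (1) / %s (2), %d points (%d on branch 1)\n",
              attr(x, "name1"), attr(x, "name2"), nrow(x), sum(x$branch == 1L)))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("Provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# points of one branch with interior compositions (used by the fitters)
branch_points <- function(dataset, branch = 1L, interior_only = TRUE) {
  stopifnot(inherits(dataset, "sle_dataset"))
  d <- as.data.frame(dataset)
  d <- d[d$branch == branch, , drop = FALSE]
  # on branch 2 the crystallizing component's mole fraction is 1 - x1
  d$x <- if (branch == 1L) d$x1 else 1 - d$x1
  if (interior_only) d <- d[d$x > 0 & d$x < 1, , drop = FALSE]
  d
}
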