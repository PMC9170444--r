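#' Partition coefficient
#'
#' Bezdek's partition coefficient `Vpc = (1/n) sum_xy b_xy^2`.  Ranges from
#' `1/f` (maximally fuzzy, uniform memberships) to 1 (crisp partition);
#' higher means a less ambiguous partition.
#'
#' @param membership `f x n` membership matrix with unit column sums.
#' @return Scalar in `[1/f, 1]`.
#' @export
partition_coefficient <- function(membership) {
  if (!is.matrix(membership) || ncol(membership) == 0) {
    ik_stop("empty membership matrix", "data")
  }
  sum(membership^2) / ncol(membership)
}

#' Partition entropy
#'
#' Bezdek's partition entropy `Vpe = -(1/n) sum_xy b_xy ln b_xy` with
#' `0 ln 0 = 0`.  Ranges from 0 (crisp) to `ln f` (uniform); lower means a
#' less ambiguous partition.
#'
#' @inheritParams partition_coefficient
#' @return Scalar in `[0, ln f]`.
#' @export
partition_entropy <- function(membership) {
  if (!is.matrix(membership) || ncol(membership) == 0) {
    ik_stop("empty membership matrix", "data")
  }
  B <- membership
  terms <- ifelse(B > 0, B * log(B), 0)
  -sum(terms) / ncol(B)
}

#' Xie-Beni index
#'
#' Compactness-to-separation ratio
#' `Vxb = sum_xy b_xy^l |m_y - a_x|^2 / (n * min_{x != e} |a_x - a_e|^2)`.
#' Lower is better: compact clusters, well-separated centers.  Invariant to
#' a common rescaling of intensities and centers.
#'
#' @inheritParams fcm_cost
#' @return Non-negative scalar.
#' @export
xie_beni <- function(image, membership, centers, fuzzifier = 2) {
  centers <- as.numeric(centers)
  if (length(centers) < 2) ik_stop("Xie-Beni needs >= 2 centers", "usage")
  sep <- min(stats::dist(centers))^2
  if (sep == 0) {
    ik_stop("degenerate centers: two cluster centers coincide", "numeric")
  }
  num <- fcm_cost(image, membership, centers, fuzzifier)
  num / (ncol(membership) * sep)
}

#' Partition-validity report
#'
#' Bundles the three indices ([partition_coefficient()],
#' [partition_entropy()], [xie_beni()]) for a fitted partition.  For a fit
#' object the indices are evaluated in the fit's own working intensity
#' space (raw intensities for classical FCM, fuzzified intensities for the
#' improved algorithm).
#'
#' @param x An `fcm_fit`/`ikfcm_fit`, or an image (with `membership`,
#'   `centers`, `fuzzifier` supplied).
#' @param ... Passed to methods.
#' @return A `validity_report` list: `vpc`, `vpe`, `vxb`, `n`, `f`.
#' @export
validity_report <- function(x, ...) UseMethod("validity_report")

#' @rdname validity_report
#' @param membership,centers,fuzzifier As in [fcm_cost()].
#' @export
validity_report.default <- function(x, membership, centers, fuzzifier = 2,
                                    ...) {
  structure(
    list(vpc = partition_coefficient(membership),
         vpe = partition_entropy(membership),
         vxb = xie_beni(x, membership, centers, fuzzifier),
         n = ncol(membership),
         f = nrow(membership)),
    class = "validity_report"
  )
}

#' @rdname validity_report
#' @export
validity_report.fcm_fit <- function(x, ...) {
  validity_report.default(x$data, x$membership, x$centers, x$fuzzifier)
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> n = ", x$n, ", f = ", x$f, "\n",
      "  Vpc = ", format(x$vpc, digits = 6),
      "  Vpe = ", format(x$vpe, digits = 6),
      "  Vxb = ", format(x$vxb, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.validity_report <- function(x, ...) {
  data.frame(vpc = x$vpc, vpe = x$vpe, vxb = x$vxb, n = x$n, f = x$f)
}
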