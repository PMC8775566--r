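#' Falconer sensitivity index of treatment response per genotype
#'
#' For each line at a given age, the sensitivity index is the line's
#' treatment response divided by the panel-average response:
#'
#' `S_i = d_i / D`, with `d_i = treated mean - control mean` for line i and
#' `D = mean(d_j)` over all lines having both treatment means.
#'
#' The index captures both magnitude and direction: `S_i > 0` means the
#' treatment moved the trait in the same direction as the panel average
#' (for a panel whose average response is an enhancement, positive values
#' indicate the trait is enhanced in that genotype); `S_i` close to 1 is an
#' average responder. Lines missing either treatment mean are excluded from
#' both the numerators and the denominator average, so the mean of `S` over
#' the reported lines is exactly 1.
#'
#' @param linemeans line-mean table (from [ls_line_means()] /
#'   [line_means_all()], or raw means) covering both treatments at `age`.
#' @param age age stratum to use.
#' @param treatments length-2 character: control and treated labels, in that
#'   order; defaults to the two labels present, taking the first
#'   (alphabetically) as control — pass explicitly when labels are not
#'   self-ordering.
#' @param tol smallest admissible |panel-average response|; below it the
#'   index is undefined for every line and an error is raised (default 1e-8).
#' @return data frame of class `sensitivity_table`: `line_id`, `age`, `d_i`
#'   (line response), `D_bar` (panel response), `S` (index).
#' @examples
#' lm_tab <- data.frame(
#'   line_id = rep(c("l1", "l2", "l3"), 2), age = "old",
#'   treatment = rep(c("control", "treated"), each = 3),
#'   lsmean = c(1, 1, 1, 3, 2, 0.5))
#' sensitivity_index(lm_tab, "old")$S    # 2.4, 1.2, -0.6
#' @export
sensitivity_index <- function(linemeans, age,
                              treatments = NULL, tol = 1e-8) {
  need <- c("line_id", "age", "treatment", "lsmean")
  miss <- setdiff(need, names(linemeans))
  if (length(miss)) {
    stopf("line-means table is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  d <- linemeans[linemeans$age == age, , drop = FALSE]
  if (is.null(treatments)) treatments <- sort(unique(d$treatment))
  if (length(treatments) != 2) {
    stopf("need exactly two treatment levels at age %s (got: %s)", age,
          paste(unique(d$treatment), collapse = ", "))
  }
  ctrl <- d[d$treatment == treatments[1], ]
  trt <- d[d$treatment == treatments[2], ]
  shared <- intersect(ctrl$line_id, trt$line_id)
  if (length(shared) < 2) {
    stopf("need at least 2 lines with both treatment means at age %s", age)
  }
  d_i <- trt$lsmean[match(shared, trt$line_id)] -
    ctrl$lsmean[match(shared, ctrl$line_id)]
  D_bar <- mean(d_i)
  if (abs(D_bar) <= tol) {
    stopf("undefined panel response: |mean treatment difference| = %.3g <= tol = %.3g",
          abs(D_bar), tol)
  }
  out <- data.frame(line_id = shared, age = age, d_i = d_i, D_bar = D_bar,
                    S = d_i / D_bar, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
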