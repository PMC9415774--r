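#' Flow matrices
#'
#' A flow matrix is a `D x D` integer matrix of inter-district move counts
#' with a zero diagonal and a `period` attribute `(start_quarter,
#' end_quarter)`.
#'
#' @param mat square numeric matrix of non-negative counts.
#' @param period integer vector `(start_quarter, end_quarter)`.
#' @export
flow_matrix <- function(mat, period = c(1L, 1L)) {
  if (nrow(mat) != ncol(mat)) stop_arg("flow matrix must be square")
  if (any(mat < 0)) stop_arg("flow counts must be non-negative")
  diag(mat) <- 0
  structure(mat, period = as.integer(period), class = c("flow_matrix", class(mat)))
}

#' @export
print.flow_matrix <- function(x, ...) {
  p <- attr(x, "period")
  cat("<flow_matrix>", nrow(x), "districts, quarters", p[1], "-", p[2],
      ", total flow", sum(x), "\n")
  invisible(x)
}

flows_from_moves <- function(from, to, D, period) {
  m <- matrix(0L, D, D)
  if (length(from)) {
    tab <- table(factor(from, levels = seq_len(D)), factor(to, levels = seq_len(D)))
    m <- matrix(as.integer(tab), D, D)
  }
  flow_matrix(m, period)
}

#' Rebuild flow matrices from recorded life histories
#'
#' Counts district changes between consecutive quarterly records of each agent
#' within the window. Summing the quarterly matrices over a year reproduces
#' the annual matrix exactly.
#'
#' @param histories a life-history data frame from [run_simulation()].
#' @param start_quarter,end_quarter window (inclusive).
#' @param aggregation `"period"` (one matrix), `"annual"` or `"quarterly"`
#'   (a list of matrices).
#' @param n_districts number of districts (inferred from the histories when
#'   missing).
#' @return a [flow_matrix()] or a list of them.
#' @export
flows_from_histories <- function(histories, start_quarter = min(histories$quarter),
                                 end_quarter = max(histories$quarter),
                                 aggregation = c("period", "annual", "quarterly"),
                                 n_districts = max(histories$district)) {
  aggregation <- match.arg(aggregation)
  h <- histories[order(histories$agent, histories$quarter), ]
  same <- c(FALSE, h$agent[-1] == h$agent[-nrow(h)])
  contiguous <- c(TRUE, diff(h$quarter) == 1)
  if (any(same & !contiguous)) stop_arg("life histories are not contiguous per agent")
  moved <- same & h$district != c(0L, h$district[-nrow(h)])
  inwin <- h$quarter >= start_quarter & h$quarter <= end_quarter
  sel <- which(moved & inwin)
  from <- h$district[sel - 1L]
  to <- h$district[sel]
  q <- h$quarter[sel]
  D <- n_districts
  if (aggregation == "period") {
    return(flows_from_moves(from, to, D, c(start_quarter, end_quarter)))
  }
  width <- if (aggregation == "annual") 4L else 1L
  starts <- seq(start_quarter, end_quarter, by = width)
  lapply(starts, function(s) {
    e <- min(s + width - 1L, end_quarter)
    keep <- q >= s & q <= e
    flows_from_moves(from[keep], to[keep], D, c(s, e))
  })
}

#' Write / read an observed-flow CSV
#'
#' Long format with header `origin,destination,mean_annual_flow`.
#'
#' @param flows a [flow_matrix()].
#' @param path file path.
#' @export
write_flows <- function(flows, path) {
  D <- nrow(flows)
  idx <- which(row(flows) != col(flows))
  df <- data.frame(
    origin = row(flows)[idx],
    destination = col(flows)[idx],
    mean_annual_flow = flows[idx]
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flows
#' @export
read_flows <- function(path) {
  df <- read.csv(path)
  D <- max(df$origin, df$destination)
  m <- matrix(0L, D, D)
  m[cbind(df$origin, df$destination)] <- df$mean_annual_flow
  flow_matrix(m)
}
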