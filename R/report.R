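## Ensemble summaries and tabular exports.

#' Summarize an ensemble of orientation results
#'
#' Per-domain angle ranges and spans, threshold counts (minimal tilting,
#' small residual translation) and per-group extremes. Deterministic given
#' its inputs.
#'
#' @param results orientation table (rows as produced by
#'   \code{\link{analyze_structure}}; columns \code{accession},
#'   \code{domain}, \code{phi}, \code{theta}, \code{dx_norm}, optionally
#'   \code{group}).
#' @param theta_thresh degrees; count of structures with theta below this.
#' @param dx_thresh Angstrom; count of structures with |dx| at or below this.
#' @return list of per-domain summaries: span, min/max phi with accessions,
#'   theta range, \code{n_low_tilt}, \code{n_small_dx}, \code{n}, and
#'   per-group phi ranges when a group column is present.
#' @export
summarize_ensemble <- function(results, theta_thresh = 1, dx_thresh = 3) {
  df <- as.data.frame(results)
  stopifnot(all(c("accession", "domain", "phi", "theta", "dx_norm") %in%
                  names(df)))
  out <- list()
  if (nrow(df) == 0) {
    warning("empty result set; nothing to summarize")
    return(out)
  }
  for (d in unique(df$domain)) {
    g <- df[df$domain == d, , drop = FALSE]
    if (nrow(g) == 0) { warning("empty domain group ", d); next }
    imin <- which.min(g$phi); imax <- which.max(g$phi)
    s <- list(n = nrow(g),
              phi_min = g$phi[imin], phi_min_accession = g$accession[imin],
              phi_max = g$phi[imax], phi_max_accession = g$accession[imax],
              phi_span = g$phi[imax] - g$phi[imin],
              theta_range = range(g$theta),
              n_low_tilt = sum(g$theta < theta_thresh),
              n_small_dx = sum(g$dx_norm <= dx_thresh))
    if (!is.null(g$group)) {
      s$by_group <- lapply(split(g, g$group), function(h)
        c(phi_min = min(h$phi), phi_max = max(h$phi), n = nrow(h)))
    }
    out[[d]] <- s
  }
  out
}

#' Radius of gyration of a point set
#'
#' Mass-uniform radius of gyration of the supplied coordinates (typically P
#' atoms): \code{sqrt(mean |x - centroid|^2)}.
#'
#' @param points N x 3 coordinate matrix (or length-3 vector).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(points) {
  if (is.null(dim(points))) return(0)
  cen <- colMeans(points)
  sqrt(mean(rowSums(sweep(points, 2, cen)^2)))
}

#' Export a two-variable scatter table
#'
#' Writes a deterministic TSV (ordered by accession) of two columns of a
#' result table, for plotting or downstream analysis.
#'
#' @param results data.frame containing \code{accession}, the two keys and
#'   optionally \code{group}.
#' @param x_key,y_key column names.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_scatter <- function(results, x_key, y_key, path) {
  df <- as.data.frame(results)
  stopifnot(all(c("accession", x_key, y_key) %in% names(df)))
  out <- df[order(df$accession),
            c("accession", x_key, y_key,
              intersect("group", names(df))), drop = FALSE]
  names(out)[2:3] <- c("x", "y")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
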