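#' @include filter.R
NULL

#' Mutation density per regulatory region
#'
#' The ranking statistic: modern-human SNCs per bp of region length,
#' computed only for regions spanning at least `minLength` bp (default
#' 1000). By default all modern SNCs count (fixed and nearly fixed);
#' `fixedOnly = TRUE` restricts the numerator to fixed changes.
#'
#' @param rset an annotated [RegulatorySet-class].
#' @param minLength minimum region length (bp) for eligibility.
#' @param fixedOnly count only fixed mSNCs in the numerator.
#' @return data.frame with one row per eligible region: `region_id`,
#'   `region_class`, `length`, `hits`, `density`.
#' @seealso [topFraction()]
#' @export
mutationDensity <- function(rset, minLength = 1000, fixedOnly = FALSE) {
    gr <- regions(rset)
    md <- mcols(gr)
    if (is.null(md$n_modern))
        stop("regions are not annotated; run annotateRegions() first")
    keep <- width(gr) >= minLength
    hits <- if (fixedOnly) md$n_modern_fixed[keep] else md$n_modern[keep]
    data.frame(region_id = md$region_id[keep],
               region_class = md$region_class[keep],
               length = width(gr)[keep],
               hits = as.integer(hits),
               density = hits / width(gr)[keep],
               stringsAsFactors = FALSE)
}

#' Flag the top density fraction per region class
#'
#' Within each class (enhancers and promoters separately, unless
#' `perClass = FALSE`), the `ceiling(fraction * n_class)` highest-density
#' regions are flagged; ceil guarantees at least one candidate from a
#' non-empty class. Boundary ties are broken deterministically: longer
#' region first, then lexicographic `region_id`.
#'
#' @param records data.frame from [mutationDensity()].
#' @param fraction top fraction to flag, in (0, 1].
#' @param perClass rank within each region class independently.
#' @return `records` with added columns `rank` (1 = densest, within class)
#'   and `top_flag`.
#' @export
topFraction <- function(records, fraction = 0.05, perClass = TRUE) {
    stopifnot(fraction > 0, fraction <= 1)
    if (nrow(records) == 0L) {
        records$rank <- integer(); records$top_flag <- logical()
        return(records)
    }
    grp <- if (perClass) records$region_class else rep("all", nrow(records))
    records$rank <- NA_integer_
    records$top_flag <- FALSE
    for (g in unique(grp)) {
        idx <- which(grp == g)
        ord <- idx[order(-records$density[idx], -records$length[idx],
                         records$region_id[idx], method = "radix")]
        records$rank[ord] <- seq_along(ord)
        nTop <- ceiling(fraction * length(idx))
        records$top_flag[ord[seq_len(nTop)]] <- TRUE
    }
    records
}
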