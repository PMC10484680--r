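#' Classify SILAC log2 ratios into per-paralog hit sets
#'
#' Splits proteins into up-/down-SUMOylated sets for SUMO-1 and SUMO-2/3
#' from their SILAC log2 ratios (treated vs mock). Comparators are
#' strict: up requires log2 ratio > +cutoff, down requires
#' log2 ratio < -cutoff; a protein exactly at the cutoff is unchanged.
#' Only proteins in the SUMOylated universe (found SUMO-conjugated in the
#' baseline characterization) are ever classified. Proteins with a
#' missing ratio are skipped for that paralog and counted.
#'
#' @param table data.frame with columns \code{protein},
#'   \code{log2RatioSumo1}, \code{log2RatioSumo23} and
#'   \code{inSumoylatedUniverse}.
#' @param cutoff positive log2-ratio cutoff (default 0.5, the ±0.5
#'   dotted-line convention).
#' @return list with elements \code{sumo23} and \code{sumo1} (each a list
#'   with \code{up} and \code{down} character vectors of protein ids) and
#'   \code{skipped}, the per-paralog count of missing ratios among
#'   universe proteins.
#' @export
classifyRatios <- function(table, cutoff = 0.5) {
    stopifnot(is.data.frame(table), cutoff > 0)
    need <- c("protein", "log2RatioSumo1", "log2RatioSumo23",
              "inSumoylatedUniverse")
    if (!all(need %in% colnames(table)))
        stop("table must have columns: ", paste(need, collapse = ", "))
    uni <- table[table$inSumoylatedUniverse, , drop = FALSE]
    one <- function(r) {
        ok <- !is.na(r)
        list(up = sort(uni$protein[ok & r > cutoff]),
             down = sort(uni$protein[ok & r < -cutoff]),
             skipped = sum(!ok))
    }
    s23 <- one(uni$log2RatioSumo23)
    s1 <- one(uni$log2RatioSumo1)
    list(sumo23 = s23[c("up", "down")],
         sumo1 = s1[c("up", "down")],
         skipped = c(sumo23 = s23$skipped, sumo1 = s1$skipped))
}

#' Flag hits confounded by protein abundance changes
#'
#' SUMOylation-change hits whose input (total proteome) abundance also
#' changed beyond the cutoff are flagged abundance-confounded — flagged,
#' not removed, since the ratio change may still be genuine.
#'
#' @param table data.frame as in [classifyRatios()], with an
#'   \code{inputAbundanceRatio} column (log2).
#' @param hits character vector of hit protein ids.
#' @param cutoff log2 abundance-change cutoff.
#' @return named logical vector over \code{hits}; all \code{NA} with a
#'   warning when the abundance column is absent.
#' @export
abundanceGuard <- function(table, hits, cutoff = 0.5) {
    stopifnot(is.data.frame(table))
    if (!"inputAbundanceRatio" %in% colnames(table)) {
        warning("no 'inputAbundanceRatio' column; abundance flags absent")
        return(stats::setNames(rep(NA, length(hits)), hits))
    }
    ab <- table$inputAbundanceRatio[match(hits, table$protein)]
    stats::setNames(!is.na(ab) & abs(ab) > cutoff, hits)
}

#' Union of two hit sets with inclusion-exclusion accounting
#'
#' Reports |A|, |B|, |A n B| and |A u B| and asserts the
#' inclusion-exclusion identity — the arithmetic behind statements such
#' as 31 SUMO-2/3 hits and 11 SUMO-1 hits with 8 in common giving 34
#' proteins in total.
#'
#' @param setA,setB character vectors of protein ids.
#' @return list with \code{sizeA}, \code{sizeB}, \code{intersectionSize},
#'   \code{unionSize} and \code{members} (the union).
#' @examples
#' unionReport(paste0("p", 1:31), paste0("p", c(1:8, 100:102)))$unionSize
#' @export
unionReport <- function(setA, setB) {
    setA <- unique(as.character(setA))
    setB <- unique(as.character(setB))
    u <- union(setA, setB)
    i <- intersect(setA, setB)
    stopifnot(length(u) == length(setA) + length(setB) - length(i))
    list(sizeA = length(setA), sizeB = length(setB),
         intersectionSize = length(i), unionSize = length(u),
         members = sort(u))
}
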