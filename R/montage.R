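#' EEG montage objects
#'
#' A montage describes the lead layout of a recording net: lead names, 2-D
#' scalp positions (head-centred, `+x` = right, `+y` = anterior), which leads
#' are excluded from analysis (cheek/neck leads), the left-right mirror
#' pairing used for lesion-side flipping, the iM1 seed set (the lead
#' overlying left primary motor cortex, classically C3, plus its six
#' neighbours), and a coarse region label per lead.
#'
#' @param leads character vector of unique lead names.
#' @param positions numeric matrix (leads x 2) of scalp coordinates.
#' @param excluded character vector of lead names dropped before analysis.
#' @param mirror named character vector mapping each lead to its left-right
#'   homologue; must be an involution (midline leads map to themselves).
#' @param seed character vector of seed lead names (iM1); none may be
#'   excluded.
#' @param region named character vector of region labels per lead, from
#'   `c("iM1","SMA","iPMv","iPAR","cTP","frontal","temporal","occipital",
#'   "other")`.
#' @return An object of class `eeg_montage`.
#' @seealso [read_montage()], [standard_montage()], [grid_montage()]
#' @export
eeg_montage <- function(leads, positions, excluded = character(),
                        mirror, seed, region = NULL) {
  leads <- as.character(leads)
  if (anyDuplicated(leads))
    stop("duplicate lead name: ", leads[duplicated(leads)][1L])
  positions <- as.matrix(positions)
  if (nrow(positions) != length(leads) || ncol(positions) != 2L)
    stop("'positions' must be a ", length(leads), " x 2 matrix")
  dimnames(positions) <- list(leads, c("x", "y"))
  excluded <- as.character(excluded)
  if (length(bad <- setdiff(excluded, leads)))
    stop("excluded lead not in montage: ", bad[1L])
  mirror <- vapply(mirror, as.character, "")
  if (length(bad <- setdiff(names(mirror), leads)))
    stop("mirror map names unknown lead: ", bad[1L])
  if (length(bad <- setdiff(leads, names(mirror))))
    stop("mirror map missing lead: ", bad[1L])
  if (length(bad <- setdiff(unname(mirror), leads)))
    stop("mirror image is not a montage lead: ", bad[1L])
  # involution: mirror(mirror(l)) == l for every lead
  twice <- unname(mirror[unname(mirror[leads])])
  if (any(ne <- twice != leads))
    stop("mirror map is not involutive at lead: ", leads[ne][1L])
  seed <- as.character(seed)
  if (length(bad <- setdiff(seed, leads)))
    stop("seed lead not in montage: ", bad[1L])
  if (length(bad <- intersect(seed, excluded)))
    stop("seed lead is flagged excluded: ", bad[1L])
  if (is.null(region)) {
    region <- stats::setNames(rep("other", length(leads)), leads)
  } else {
    region <- vapply(region, as.character, "")
    if (length(bad <- setdiff(leads, names(region))))
      stop("region label missing for lead: ", bad[1L])
    region <- region[leads]
  }
  known <- c("iM1", "SMA", "iPMv", "iPAR", "cTP", "frontal", "temporal",
             "occipital", "other")
  if (length(bad <- setdiff(unique(region), known)))
    stop("unknown region label: ", bad[1L])
  structure(
    list(leads = leads, positions = positions, excluded = excluded,
         mirror = mirror, seed = seed, region = region),
    class = "eeg_montage")
}

#' Read or write a montage JSON file
#'
#' The montage file is a JSON object with members `leads` (array of names),
#' `positions` (array of `[x, y]` pairs in lead order), `excluded` (array of
#' names), `mirror` (object lead -> homologue), `seed` (array of names) and
#' `region` (object lead -> label).  All montage invariants are validated on
#' read; violations raise an error naming the offending lead.
#'
#' @param path file path.
#' @return `read_montage()` returns an `eeg_montage`; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("leads", "positions", "mirror", "seed"))
    if (is.null(j[[f]])) stop("montage file missing field '", f, "'")
  eeg_montage(leads = j$leads,
              positions = j$positions,
              excluded = if (is.null(j$excluded)) character() else j$excluded,
              mirror = unlist(j$mirror),
              seed = j$seed,
              region = if (is.null(j$region)) NULL else unlist(j$region))
}

#' @rdname read_montage
#' @param montage an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  j <- list(leads = montage$leads,
            positions = unname(montage$positions),
            excluded = montage$excluded,
            mirror = as.list(montage$mirror),
            seed = montage$seed,
            region = as.list(montage$region))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analyzable (non-excluded) leads of a montage
#' @param montage an `eeg_montage`.
#' @return character vector of lead names, in montage order.
#' @export
analysis_leads <- function(montage) {
  setdiff(montage$leads, montage$excluded)
}

#' Rectangular grid montage
#'
#' Builds a montage on an `nrow` x `ncol` grid of scalp positions with exact
#' left-right mirror symmetry.  Row 1 is the most anterior row; columns run
#' left to right.  Optionally the bottom `exclude_rows` rows are flagged as
#' excluded, emulating cheek/neck leads of a dense-array net.  The seed set
#' is the non-excluded lead nearest the canonical C3 position (left central
#' scalp)
#' together with its six nearest non-excluded neighbours.  Region labels are
#' assigned from position (see Details).
#'
#' @details Region labels: seed leads are `iM1`; midline anterior-central
#'   leads `SMA`; left lateral frontal-central `iPMv`; left parietal `iPAR`;
#'   right (contralesional, after flipping) temporal-parietal `cTP`; the
#'   anterior-most rows `frontal`, posterior-most `occipital`, far-lateral
#'   mid rows `temporal`; everything else (including excluded leads)
#'   `other`.  Labels are coarse scalp regions for interpretation only.
#'
#' @param nrow,ncol grid dimensions.
#' @param exclude_rows number of bottom (posterior/neck) rows to exclude.
#' @param prefix lead-name prefix; names are `<prefix><index>` zero-padded,
#'   row-major.
#' @return An `eeg_montage` with `nrow * ncol` leads.
#' @export
grid_montage <- function(nrow, ncol, exclude_rows = 0L, prefix = "E") {
  stopifnot(nrow >= 2L, ncol >= 2L, exclude_rows >= 0L, exclude_rows < nrow)
  n <- nrow * ncol
  pad <- nchar(as.character(n))
  leads <- sprintf(paste0(prefix, "%0", pad, "d"), seq_len(n))
  xs <- seq(-1, 1, length.out = ncol)
  ys <- seq(1, -1, length.out = nrow)
  pos <- cbind(x = rep(xs, times = nrow), y = rep(ys, each = ncol))
  row_of <- rep(seq_len(nrow), each = ncol)
  col_of <- rep(seq_len(ncol), times = nrow)
  excluded <- leads[row_of > nrow - exclude_rows]
  mirror_idx <- (row_of - 1L) * ncol + (ncol + 1L - col_of)
  mirror <- stats::setNames(leads[mirror_idx], leads)
  keep <- !(leads %in% excluded)
  d2 <- (pos[, 1] + 0.45)^2 + (pos[, 2] - 0.1)^2
  d2[!keep] <- Inf
  centre <- which.min(d2)
  dn <- (pos[, 1] - pos[centre, 1])^2 + (pos[, 2] - pos[centre, 2])^2
  dn[!keep] <- Inf
  dn[centre] <- Inf
  seed <- leads[c(centre, order(dn)[1:6])]
  region <- .grid_regions(leads, pos, keep, seed)
  eeg_montage(leads, pos, excluded, mirror, seed, region)
}

# Position-rule region labels.  The anterior-posterior coordinate is
# normalized over the analyzable (non-excluded) scalp so the same rules
# work whether or not a cheek/neck ring is excluded; thresholds chosen so
# every named region is non-empty on 8x8 and 16x16 grids.
.grid_regions <- function(leads, pos, keep, seed) {
  x <- pos[, 1]; y <- pos[, 2]
  yr <- range(y[keep])
  yn <- (y - yr[1]) / diff(yr)
  region <- rep("other", length(leads))
  region[yn >= 0.80] <- "frontal"
  region[yn <= 0.10] <- "occipital"
  region[abs(x) <= 0.16 & yn > 0.55 & yn < 0.80] <- "SMA"
  region[x <= -0.55 & yn > 0.55 & yn < 0.80] <- "iPMv"
  region[x <= -0.12 & x > -0.70 & yn > 0.15 & yn < 0.45] <- "iPAR"
  region[abs(x) >= 0.80 & yn > 0.30 & yn < 0.65] <- "temporal"
  region[x >= 0.30 & yn > 0.10 & yn < 0.45] <- "cTP"
  region[!keep] <- "other"
  region[leads %in% seed] <- "iM1"
  stats::setNames(region, leads)
}

#' Paper-standard 256-lead montage
#'
#' A dense-array montage emulating a 256-lead net: a 16 x 16 scalp grid
#' whose bottom four rows (64 leads, cheek/neck) are excluded, leaving 192
#' analyzable leads, with a 7-lead iM1 seed set over left motor cortex.
#'
#' @return An `eeg_montage` with 256 leads.
#' @export
standard_montage <- function() {
  grid_montage(16L, 16L, exclude_rows = 4L)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$leads), " leads (",
      length(x$excluded), " excluded, ",
      length(analysis_leads(x)), " analyzable), seed: ",
      paste(x$seed, collapse = " "), "\n", sep = "")
  tab <- table(x$region[analysis_leads(x)])
  cat("regions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
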