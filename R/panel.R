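#' Construct a genotype panel
#'
#' A genotype panel holds diploid SSR calls for a set of lines. Each call is
#' an unordered pair of allele sizes (PCR amplicon lengths in base pairs);
#' a single size denotes a homozygote. Allele identity is the exact integer
#' size: no binning is applied.
#'
#' @param line_ids character vector of unique line identifiers.
#' @param a1,a2 integer matrices (lines x markers) holding the two allele
#'   sizes of each call; `NA` in both marks a missing call. Within a cell the
#'   pair is unordered; the constructor stores `pmin`/`pmax` canonically.
#' @param markers data frame of marker metadata with columns `marker_id`,
#'   `linkage_group`, `position_cM`, `marker_class`. If `NULL`, a skeleton
#'   with unknown map positions is built from the column names of `a1`.
#' @param max_alleles maximum number of distinct alleles tolerated per locus.
#' @param missing_cap maximum tolerated fraction of missing calls per locus.
#' @return an object of class `genotype_panel` with elements `line_ids`,
#'   `markers`, `a1`, `a2`.
#' @export
genotype_panel <- function(line_ids, a1, a2, markers = NULL,
                           max_alleles = 8, missing_cap = 0.2) {
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids))
    stop("duplicate line ids: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 dimensions differ")
  if (nrow(a1) != length(line_ids)) stop("line_ids length != nrow(a1)")
  if (is.null(markers)) {
    ids <- colnames(a1)
    if (is.null(ids)) ids <- sprintf("M%03d", seq_len(ncol(a1)))
    markers <- data.frame(marker_id = ids,
                          linkage_group = NA_character_,
                          position_cM = NA_real_,
                          marker_class = "genomic_ssr",
                          stringsAsFactors = FALSE)
  }
  markers <- validate_marker_defs(markers)
  if (nrow(markers) != ncol(a1)) stop("markers rows != ncol(a1)")
  if (xor(any(is.na(a1)), any(is.na(a2))) ||
      !identical(which(is.na(a1)), which(is.na(a2))))
    stop("missingness must affect both allele copies of a call")
  bad <- which(!is.na(a1) & (a1 <= 0L | a2 <= 0L))
  if (length(bad)) stop("allele sizes must be positive integers")
  # canonical unordered storage
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  a1 <- lo; a2 <- hi
  dimnames(a1) <- dimnames(a2) <- list(line_ids, markers$marker_id)
  for (j in seq_len(ncol(a1))) {
    n_all <- length(unique(c(a1[, j], a2[, j])[!is.na(c(a1[, j], a2[, j]))]))
    if (n_all < 1)
      stop("locus ", markers$marker_id[j], " has no non-missing calls")
    if (n_all > max_alleles)
      stop("locus ", markers$marker_id[j], " has ", n_all,
           " alleles, exceeding max_alleles = ", max_alleles)
    miss <- mean(is.na(a1[, j]))
    if (miss > missing_cap)
      stop("locus ", markers$marker_id[j], " missing fraction ",
           signif(miss, 3), " exceeds cap ", missing_cap)
  }
  structure(list(line_ids = line_ids, markers = markers, a1 = a1, a2 = a2),
            class = "genotype_panel")
}

validate_marker_defs <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("marker_id", "linkage_group", "position_cM", "marker_class")
  for (nm in setdiff(need, names(markers)))
    markers[[nm]] <- if (nm == "position_cM") NA_real_ else NA_character_
  markers <- markers[, need]
  markers$marker_id <- as.character(markers$marker_id)
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids in marker metadata")
  ok_class <- c("genomic_ssr", "est_ssr", "genic")
  mc <- markers$marker_class
  if (any(!is.na(mc) & !mc %in% ok_class))
    stop("marker_class must be one of ", paste(ok_class, collapse = ", "))
  # a map position only makes sense on a linkage group
  orphan <- !is.na(markers$position_cM) & is.na(markers$linkage_group)
  if (any(orphan))
    stop("position_cM without linkage_group for: ",
         paste(markers$marker_id[orphan], collapse = ", "))
  if (any(!is.na(markers$position_cM) & markers$position_cM < 0))
    stop("position_cM must be nonnegative")
  markers
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$line_ids), "lines x",
      nrow(x$markers), "markers\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(length(x$line_ids), nrow(x$markers))

#' Index alleles of a panel
#'
#' Maps each allele size to a per-locus integer index (1-based, in increasing
#' size order) and to a global index over all (locus, allele) levels. This is
#' the internal representation consumed by the admixture EM and LD kernels.
#'
#' @param panel a [genotype_panel()].
#' @return list with `alleles` (list of sorted allele sizes per locus),
#'   `n_alleles` (integer per locus), `i1`, `i2` (lines x loci matrices of
#'   per-locus allele indices, `NA` for missing), `offset` (0-based global
#'   offset of each locus's allele block).
#' @export
panel_allele_index <- function(panel) {
  L <- ncol(panel$a1)
  alleles <- vector("list", L)
  i1 <- panel$a1; i2 <- panel$a2
  for (j in seq_len(L)) {
    sizes <- sort(unique(c(panel$a1[, j], panel$a2[, j])))
    sizes <- sizes[!is.na(sizes)]
    alleles[[j]] <- sizes
    i1[, j] <- match(panel$a1[, j], sizes)
    i2[, j] <- match(panel$a2[, j], sizes)
  }
  n_alleles <- lengths(alleles)
  list(alleles = alleles, n_alleles = n_alleles, i1 = i1, i2 = i2,
       offset = c(0L, cumsum(n_alleles))[seq_len(L)])
}

#' Per-locus allele frequencies
#'
#' Frequencies are counted over allele copies (two per non-missing diploid
#' call), the standard population-genetic convention.
#'
#' @param panel a [genotype_panel()].
#' @return list of named numeric vectors (names are allele sizes), one per
#'   locus, each summing to 1.
#' @export
allele_frequencies <- function(panel) {
  idx <- panel_allele_index(panel)
  out <- vector("list", ncol(panel$a1))
  names(out) <- panel$markers$marker_id
  for (j in seq_along(out)) {
    cnt <- tabulate(c(idx$i1[, j], idx$i2[, j]), nbins = idx$n_alleles[j])
    p <- cnt / sum(cnt)
    names(p) <- idx$alleles[[j]]
    out[[j]] <- p
  }
  out
}

#' Subset a panel by lines and/or markers
#' @param panel a [genotype_panel()].
#' @param lines,markers indices, logical masks or names selecting rows/loci.
#' @return a [genotype_panel()].
#' @export
subset_panel <- function(panel, lines = NULL, markers = NULL) {
  li <- if (is.null(lines)) seq_along(panel$line_ids) else lines
  mj <- if (is.null(markers)) seq_len(nrow(panel$markers)) else markers
  if (is.character(li)) li <- match(li, panel$line_ids)
  if (is.character(mj)) mj <- match(mj, panel$markers$marker_id)
  genotype_panel(panel$line_ids[li],
                 panel$a1[li, mj, drop = FALSE],
                 panel$a2[li, mj, drop = FALSE],
                 markers = panel$markers[mj, , drop = FALSE],
                 missing_cap = 1)
}
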