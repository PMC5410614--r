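#' Read a wide-format SSR genotype table
#'
#' Expects a TSV whose first column is the line identifier and remaining
#' columns are markers. Cells are `"a/b"` for a heterozygote, `"a"` for a
#' homozygote (expanded to the pair `a/a`), or the missing token.
#'
#' @param path file path.
#' @param missing_token string marking a missing call (default `"NA"`).
#' @param markers optional marker metadata data frame (see
#'   [read_marker_map()]); matched to columns by `marker_id`.
#' @param max_alleles,missing_cap validation limits passed to
#'   [genotype_panel()].
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, missing_token = "NA", markers = NULL,
                           max_alleles = 8, missing_cap = 0.2) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  if (ncol(raw) < 2) stop("genotype table needs a line column and >=1 marker")
  line_ids <- raw[[1]]
  if (anyDuplicated(line_ids))
    stop("duplicate line id in genotype file: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  marker_ids <- names(raw)[-1]
  n <- length(line_ids); L <- length(marker_ids)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    cells <- raw[[j + 1]]
    miss <- cells == missing_token | cells == ""
    parts <- strsplit(cells[!miss], "/", fixed = TRUE)
    bad <- vapply(parts, function(p)
      length(p) > 2 || anyNA(suppressWarnings(as.integer(p))), logical(1))
    if (any(bad)) {
      i <- which(!miss)[which(bad)[1]]
      stop("cannot parse allele token '", cells[i], "' at line ",
           line_ids[i], ", marker ", marker_ids[j])
    }
    v1 <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    v2 <- vapply(parts, function(p) as.integer(p[length(p)]), integer(1))
    a1[!miss, j] <- v1
    a2[!miss, j] <- v2
  }
  colnames(a1) <- colnames(a2) <- marker_ids
  if (!is.null(markers)) {
    markers <- validate_marker_defs(markers)
    hit <- match(marker_ids, markers$marker_id)
    if (anyNA(hit))
      stop("markers absent from metadata: ",
           paste(marker_ids[is.na(hit)], collapse = ", "))
    markers <- markers[hit, , drop = FALSE]
  }
  genotype_panel(line_ids, a1, a2, markers = markers,
                 max_alleles = max_alleles, missing_cap = missing_cap)
}

#' Write a genotype panel as a wide TSV
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @param missing_token token written for missing calls.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, missing_token = "NA") {
  cells <- matrix(missing_token, nrow(panel$a1), ncol(panel$a1))
  ok <- !is.na(panel$a1)
  hom <- ok & panel$a1 == panel$a2
  cells[hom] <- as.character(panel$a1[hom])
  het <- ok & panel$a1 != panel$a2
  cells[het] <- paste0(panel$a1[het], "/", panel$a2[het])
  df <- data.frame(line = panel$line_ids, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("line", panel$markers$marker_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker metadata
#'
#' CSV with columns `marker_id,linkage_group,position_cM,marker_class`.
#' `marker_class` is one of `genomic_ssr`, `est_ssr`, `genic`.
#' @param path file path.
#' @return validated data frame.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$position_cM <- suppressWarnings(as.numeric(df$position_cM))
  df$linkage_group[df$linkage_group %in% c("", "NA")] <- NA_character_
  validate_marker_defs(df)
}

#' @rdname read_marker_map
#' @param markers validated marker data frame.
#' @export
write_marker_map <- function(markers, path) {
  utils::write.csv(validate_marker_defs(markers), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

.locations <- c("Delhi", "Jodhpur", "Dharwad")
.traits <- c("Fe", "Zn")

#' Read a long-format phenotype table
#'
#' CSV with columns `line,location,year,replicate,trait,value`; values are
#' grain mineral concentrations in ppm. Locations are `Delhi`, `Jodhpur`,
#' `Dharwad`; traits `Fe` and `Zn`.
#'
#' @param path file path.
#' @param panel optional [genotype_panel()]; phenotyped lines missing from
#'   the panel are reported as a warning.
#' @return validated data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phenotype_table(df, panel = panel)
}

#' Validate a phenotype data frame
#' @param df data frame with columns `line,location,year,replicate,trait,value`.
#' @param panel optional companion [genotype_panel()] for line cross-checks.
#' @return the validated data frame, classed `phenotype_table`.
#' @export
phenotype_table <- function(df, panel = NULL) {
  need <- c("line", "location", "year", "replicate", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns ", paste(need, collapse = ","))
  df <- df[, need]
  df$line <- as.character(df$line)
  if (any(!df$location %in% .locations))
    stop("unknown location(s): ",
         paste(setdiff(unique(df$location), .locations), collapse = ", "))
  if (any(!df$trait %in% .traits))
    stop("unknown trait(s): ",
         paste(setdiff(unique(df$trait), .traits), collapse = ", "))
  df$year <- as.integer(df$year)
  df$replicate <- as.integer(df$replicate)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value) || any(df$value <= 0))
    stop("phenotype values must be positive ppm")
  key <- paste(df$line, df$location, df$year, df$replicate, df$trait)
  if (anyDuplicated(key))
    stop("duplicate phenotype record(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  if (!is.null(panel)) {
    orphans <- setdiff(unique(df$line), panel$line_ids)
    if (length(orphans))
      warning("phenotyped lines absent from panel: ",
              paste(utils::head(orphans, 5), collapse = ", "))
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param pheno a phenotype table.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a Q matrix (admixture proportions)
#'
#' CSV with a `line` column then `q1..qK`. Rows must sum to 1.
#' @param path file path.
#' @return for the reader, a `q_matrix` (see [q_matrix()]).
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  q <- as.matrix(df[, -1, drop = FALSE])
  q_matrix(df[[1]], q)
}

#' @rdname read_q_matrix
#' @param Q a `q_matrix`.
#' @export
write_q_matrix <- function(Q, path) {
  df <- data.frame(line = Q$line_ids, Q$q, check.names = FALSE)
  names(df) <- c("line", paste0("q", seq_len(Q$K)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a labeled square kinship matrix as CSV
#' @param path file path.
#' @return the reader returns a symmetric numeric matrix with line ids as
#'   dimnames.
#' @export
read_kinship <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- df[[1]]
  if (nrow(k) != ncol(k)) stop("kinship matrix must be square")
  if (max(abs(k - t(k))) > 1e-8) stop("kinship matrix must be symmetric")
  k
}

#' @rdname read_kinship
#' @param k symmetric matrix with dimnames.
#' @export
write_kinship <- function(k, path) {
  df <- data.frame(line = rownames(k), k, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as TSV
#'
#' Generic writer used for marker-trait association records, allele effects
#' and cross proposals. Columns keep their data-frame order; numeric columns
#' are serialized with 10 significant digits so reports round-trip.
#'
#' @param records data frame (possibly zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
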