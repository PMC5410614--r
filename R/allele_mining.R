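#' Per-allele phenotypic effects at significant markers
#'
#' For each allele `i` of each marker, the effect is
#' `a_i = mean(trait over carrier lines) - mean(trait over all lines with a
#' non-missing call at the marker)` (the population-mean baseline used in
#' place of null alleles). Positive `a_i` marks a favorable allele.
#' Heterozygous lines contribute their full phenotype to each carried allele
#' class; with complete data and fully homozygous lines the identity
#' `sum_i n_i a_i = 0` is exact.
#'
#' @param panel a [genotype_panel()].
#' @param dataset named numeric vector of line-level trait values (ppm).
#' @param markers character vector of significant marker ids.
#' @param trait,dataset_name labels copied into the records.
#' @param top_carriers how many carrier lines to list (ranked by trait
#'   value, best first).
#' @return data frame `(marker_id, allele, trait, dataset, a_i, n_i,
#'   carriers)`; `carriers` is a comma-separated ranked line list.
#' @export
allele_effects <- function(panel, dataset, markers, trait = NA_character_,
                           dataset_name = NA_character_, top_carriers = 3) {
  js <- match(markers, panel$markers$marker_id)
  if (anyNA(js)) stop("unknown marker(s): ",
                      paste(markers[is.na(js)], collapse = ", "))
  rows <- list()
  for (j in js) {
    a1 <- panel$a1[, j]; a2 <- panel$a2[, j]
    has_data <- !is.na(a1) & panel$line_ids %in% names(dataset)
    lines <- panel$line_ids[has_data]
    vals <- dataset[lines]
    pop_mean <- mean(vals)
    sizes <- sort(unique(c(a1[has_data], a2[has_data])))
    for (s in sizes) {
      carrier <- has_data & (a1 == s | a2 == s)
      cl <- panel$line_ids[carrier]
      cv <- dataset[cl]
      a_i <- if (length(sizes) == 1) 0 else mean(cv) - pop_mean
      ranked <- cl[order(cv, decreasing = TRUE)]
      rows[[length(rows) + 1]] <- data.frame(
        marker_id = panel$markers$marker_id[j], allele = s,
        trait = trait, dataset = dataset_name,
        a_i = a_i, n_i = length(cl),
        carriers = paste(utils::head(ranked, top_carriers), collapse = ", "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Filter favorable alleles by minimum effect
#'
#' Retains alleles with positive effect at least `min_effect` (default 0:
#' every positive-effect allele; 4 ppm is the usual cross-planning cut),
#' sorted by decreasing effect.
#'
#' @param effects data frame from [allele_effects()].
#' @param min_effect minimum effect in ppm.
#' @return filtered, sorted data frame.
#' @export
favorable_alleles <- function(effects, min_effect = 0) {
  keep <- effects$a_i > 0 & effects$a_i >= min_effect
  out <- effects[keep, , drop = FALSE]
  out[order(-out$a_i), , drop = FALSE]
}

#' Favorable-allele inventory per line
#'
#' Counts, per line, the distinct favorable (marker, allele) pairs it
#' carries, per trait and combined (a pair favorable for both traits counts
#' once in the combined tally).
#'
#' @param panel a [genotype_panel()].
#' @param favorable data frame from [favorable_alleles()] (nonempty).
#' @return list with `counts` (data frame line x `n_Fe`, `n_Zn`, `n_total`)
#'   and `sets` (per line, the character vector of carried
#'   `"marker:allele"` keys, named by trait membership attribute).
#' @export
genotype_allele_inventory <- function(panel, favorable) {
  if (!nrow(favorable)) stop("favorable allele list is empty")
  fav <- unique(favorable[, c("marker_id", "allele", "trait")])
  fav$key <- paste0(fav$marker_id, ":", fav$allele)
  sets <- lapply(panel$line_ids, function(line) {
    i <- match(line, panel$line_ids)
    carried <- vapply(seq_len(nrow(fav)), function(r) {
      j <- match(fav$marker_id[r], panel$markers$marker_id)
      !is.na(panel$a1[i, j]) &&
        (panel$a1[i, j] == fav$allele[r] || panel$a2[i, j] == fav$allele[r])
    }, logical(1))
    fav[carried, c("key", "trait")]
  })
  names(sets) <- panel$line_ids
  counts <- data.frame(
    line = panel$line_ids,
    n_Fe = vapply(sets, function(s) length(unique(s$key[s$trait == "Fe"])),
                  integer(1)),
    n_Zn = vapply(sets, function(s) length(unique(s$key[s$trait == "Zn"])),
                  integer(1)),
    n_total = vapply(sets, function(s) length(unique(s$key)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, sets = sets)
}

#' Propose crosses that pyramid favorable alleles
#'
#' Scores every unordered line pair by the size of the union of the two
#' parents' favorable (marker, allele) sets and returns the best `top_n`,
#' ties broken lexicographically by parent ids. Per-trait predicted counts
#' are the union sizes within each trait.
#'
#' @param inventory result of [genotype_allele_inventory()].
#' @param top_n number of crosses to return.
#' @return data frame `(parent1, parent2, n_Fe, n_Zn, n_total)`.
#' @export
propose_crosses <- function(inventory, top_n = 10) {
  sets <- inventory$sets
  lines <- names(sets)
  if (length(lines) < 2) stop("need >= 2 lines")
  pairs <- utils::combn(seq_along(lines), 2)
  score <- function(ix) {
    u <- rbind(sets[[ix[1]]], sets[[ix[2]]])
    c(n_Fe = length(unique(u$key[u$trait == "Fe"])),
      n_Zn = length(unique(u$key[u$trait == "Zn"])),
      n_total = length(unique(u$key)))
  }
  sc <- apply(pairs, 2, score)
  out <- data.frame(parent1 = lines[pairs[1, ]], parent2 = lines[pairs[2, ]],
                    n_Fe = sc["n_Fe", ], n_Zn = sc["n_Zn", ],
                    n_total = sc["n_total", ], stringsAsFactors = FALSE)
  out <- out[order(-out$n_total, out$parent1, out$parent2), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
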