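.loc_prefix <- c(Delhi = "Del", Jodhpur = "Jod", Dharwad = "DW")

#' Assemble the twelve analysis datasets for one trait
#'
#' Environment datasets are per-line replicate means in each location-year
#' (`Del-14`, `Del-15`, `Jod-14`, `Jod-15`, `DW-14`, `DW-15`); pooled
#' datasets are unweighted means of their constituent environments:
#' per-location means (`Del-M`, `Jod-M`, `DW-M`), per-year means
#' (`Y14-M`, `Y15-M`) and the grand mean `GM`. Lines missing an entire
#' environment are dropped, with a warning, from pooled datasets involving
#' that environment.
#'
#' @param pheno a `phenotype_table`.
#' @param trait `"Fe"` or `"Zn"`.
#' @return named list of 12 named numeric vectors (line -> trait mean, ppm).
#' @export
build_datasets <- function(pheno, trait) {
  stopifnot(trait %in% .traits)
  df <- pheno[pheno$trait == trait, ]
  if (!nrow(df)) stop("no records for trait ", trait)
  locs <- sort(unique(df$location))
  years <- sort(unique(df$year))
  env_name <- function(loc, yr) paste0(.loc_prefix[[loc]], "-", substr(yr, 3, 4))
  envs <- list()
  for (loc in .locations[.locations %in% locs]) for (yr in years) {
    sub <- df[df$location == loc & df$year == yr, ]
    if (!nrow(sub)) next
    envs[[env_name(loc, yr)]] <- c(tapply(sub$value, sub$line, mean))
  }
  pool <- function(names_in) {
    common <- Reduce(intersect, lapply(envs[names_in], names))
    all_lines <- Reduce(union, lapply(envs[names_in], names))
    if (length(common) < length(all_lines))
      warning("lines missing an environment excluded from pooled dataset: ",
              paste(utils::head(setdiff(all_lines, common), 5), collapse = ", "))
    rowMeans(do.call(cbind, lapply(envs[names_in], `[`, common)))
  }
  out <- envs
  for (loc in .locations[.locations %in% locs]) {
    nm <- paste0(.loc_prefix[[loc]], "-M")
    members <- grep(paste0("^", .loc_prefix[[loc]], "-\\d"), names(envs),
                    value = TRUE)
    out[[nm]] <- pool(members)
  }
  for (yr in years) {
    suffix <- paste0("-", substr(yr, 3, 4))
    members <- names(envs)[endsWith(names(envs), suffix)]
    out[[paste0("Y", substr(yr, 3, 4), "-M")]] <- pool(members)
  }
  out[["GM"]] <- pool(names(envs))
  out
}

#' Combined two-way ANOVA variance components across environments
#'
#' Genotype-by-environment ANOVA over replicate plot values (environments =
#' location-year combinations), with method-of-moments extraction from
#' expected mean squares: `sigma_e2 = MS_error`,
#' `sigma_GE2 = (MS_GE - MS_error) / r`,
#' `sigma_G2 = (MS_G - MS_GE) / (n r)`; negatives are clamped to zero.
#'
#' @param pheno a `phenotype_table`.
#' @param trait `"Fe"` or `"Zn"`.
#' @return list of class `variance_components`: `sigma_G2`, `sigma_GE2`,
#'   `sigma_e2`, `r` (replicates), `n_env`, and the mean-squares table.
#' @export
combined_anova <- function(pheno, trait) {
  df <- pheno[pheno$trait == trait, ]
  if (!nrow(df)) stop("no records for trait ", trait)
  df$env <- factor(paste(df$location, df$year))
  df$line <- factor(df$line)
  n_env <- nlevels(df$env)
  if (n_env < 2) stop("need >= 2 environments")
  reps <- table(df$line, df$env)
  if (any(reps < 2)) stop("need >= 2 replicates in every line x environment cell")
  r <- mean(reps)
  fit <- stats::lm(value ~ line + env + line:env, data = df)
  an <- stats::anova(fit)
  ms <- an[["Mean Sq"]]; names(ms) <- rownames(an)
  sigma_e2 <- ms[["Residuals"]]
  sigma_GE2 <- max((ms[["line:env"]] - sigma_e2) / r, 0)
  sigma_G2 <- max((ms[["line"]] - ms[["line:env"]]) / (n_env * r), 0)
  structure(list(sigma_G2 = sigma_G2, sigma_GE2 = sigma_GE2,
                 sigma_e2 = sigma_e2, r = r, n_env = n_env,
                 anova = an),
            class = "variance_components")
}

#' Single-environment ANOVA variance components
#'
#' One-way genotype ANOVA within one location-year:
#' `sigma_e2 = MS_error`, `sigma_G2 = (MS_G - MS_error) / r`.
#'
#' @param pheno a `phenotype_table`.
#' @param trait `"Fe"` or `"Zn"`.
#' @param location,year environment selector.
#' @return a `variance_components` list (with `sigma_GE2 = 0`, `n_env = 1`).
#' @export
single_env_anova <- function(pheno, trait, location, year) {
  df <- pheno[pheno$trait == trait & pheno$location == location &
                pheno$year == year, ]
  if (!nrow(df)) stop("no records for that environment")
  df$line <- factor(df$line)
  reps <- table(df$line)
  if (any(reps < 2)) stop("need >= 2 replicates per line")
  r <- mean(reps)
  an <- stats::anova(stats::lm(value ~ line, data = df))
  sigma_e2 <- an["Residuals", "Mean Sq"]
  sigma_G2 <- max((an["line", "Mean Sq"] - sigma_e2) / r, 0)
  structure(list(sigma_G2 = sigma_G2, sigma_GE2 = 0, sigma_e2 = sigma_e2,
                 r = r, n_env = 1L, anova = an),
            class = "variance_components")
}

#' Broad-sense heritability from variance components
#'
#' Single environment: `H2 = sigma_G2 / (sigma_G2 + sigma_e2 / r)`.
#' Multi environment:
#' `H2 = sigma_G2 / (sigma_G2 + sigma_GE2 / n + sigma_e2 / (n r))`.
#'
#' @param vc a `variance_components` list (or any list with the fields).
#' @param mode `"single"` or `"multi"`.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(vc, mode = c("multi", "single")) {
  mode <- match.arg(mode)
  r <- vc$r
  denom <- if (mode == "single") vc$sigma_G2 + vc$sigma_e2 / r
  else vc$sigma_G2 + vc$sigma_GE2 / vc$n_env + vc$sigma_e2 / (vc$n_env * r)
  if (denom == 0) stop("all variance components are zero; H2 undefined")
  vc$sigma_G2 / denom
}

#' Descriptive statistics table across the twelve datasets
#'
#' Min, max, mean and standard error of the mean per dataset, plus
#' broad-sense heritability for the six single environments (single-
#' environment formula) and the grand mean (multi-environment formula).
#'
#' @param pheno a `phenotype_table`.
#' @param trait `"Fe"` or `"Zn"`.
#' @return data frame with one row per dataset.
#' @export
describe_datasets <- function(pheno, trait) {
  ds <- build_datasets(pheno, trait)
  h2 <- rep(NA_real_, length(ds)); names(h2) <- names(ds)
  for (loc in .locations) for (yr in sort(unique(pheno$year))) {
    nm <- paste0(.loc_prefix[[loc]], "-", substr(yr, 3, 4))
    if (nm %in% names(ds))
      h2[nm] <- heritability(single_env_anova(pheno, trait, loc, yr), "single")
  }
  if ("GM" %in% names(ds))
    h2["GM"] <- heritability(combined_anova(pheno, trait), "multi")
  data.frame(dataset = names(ds),
             n = vapply(ds, length, integer(1)),
             min = vapply(ds, min, numeric(1)),
             max = vapply(ds, max, numeric(1)),
             mean = vapply(ds, mean, numeric(1)),
             SEm = vapply(ds, function(v) stats::sd(v) / sqrt(length(v)),
                          numeric(1)),
             H2 = h2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of a trait dataset with population structure
#'
#' Multiple regression of the line-level trait vector on the first K-1
#' ancestry columns; reports the model R-squared and the overall F-test
#' p-value. With K = 1 the structure explains nothing by definition.
#'
#' @param Q a [q_matrix()].
#' @param dataset named numeric vector of line-level trait values.
#' @return list `(R2, p, df1, df2)`.
#' @export
structure_trait_correlation <- function(Q, dataset) {
  lines <- intersect(Q$line_ids, names(dataset))
  if (length(lines) < 3) stop("too few lines shared between Q and dataset")
  if (Q$K == 1) return(list(R2 = 0, p = NA_real_, df1 = 0L,
                            df2 = length(lines) - 1L))
  y <- dataset[lines]
  X <- Q$q[match(lines, Q$line_ids), -Q$K, drop = FALSE]
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(R2 = sm$r.squared, p = unname(p),
       df1 = unname(fstat[2]), df2 = unname(fstat[3]))
}
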