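#' Read a phenotype/covariate table
#'
#' Reads a TSV with one row per sample, extracts the response and covariates,
#' drops rows with a missing response, and returns them in the order of
#' `sample_ids` (typically the fam order of the genotype file). An intercept
#' column is always prepended to the covariate matrix.
#'
#' @param path TSV path; must contain an `IID` sample-id column.
#' @param pheno_col name of the response column.
#' @param covar_cols character vector of covariate column names (may be empty).
#' @param trait_type `"binary"` (response coded 0/1) or `"quantitative"`.
#' @param sample_ids optional character vector fixing sample order; samples
#'   absent from the table are dropped with a message.
#' @return A `phenotype_table`: list with `sample_ids`, `Y`, `X` (including
#'   the intercept column), `trait_type`.
#' @export
read_phenotypes <- function(path, pheno_col, covar_cols = character(),
                            trait_type = c("binary", "quantitative"),
                            sample_ids = NULL) {
  trait_type <- match.arg(trait_type)
  tab <- data.table::fread(path, data.table = FALSE)
  if (!"IID" %in% names(tab)) stop("phenotype file needs an IID column")
  miss <- setdiff(c(pheno_col, covar_cols), names(tab))
  if (length(miss)) stop("phenotype file lacks columns: ",
                         paste(miss, collapse = ", "))
  tab <- tab[!is.na(tab[[pheno_col]]), , drop = FALSE]
  if (!is.null(sample_ids)) {
    keep <- intersect(sample_ids, tab$IID)
    if (length(keep) < length(sample_ids))
      message(length(sample_ids) - length(keep),
              " genotyped samples lack phenotypes and were dropped")
    tab <- tab[match(keep, tab$IID), , drop = FALSE]
  }
  phenotype_table(tab$IID, tab[[pheno_col]],
                  X = as.matrix(tab[, covar_cols, drop = FALSE]),
                  trait_type = trait_type)
}

#' Construct a phenotype table
#'
#' @param sample_ids character sample identifiers.
#' @param Y response vector (0/1 for binary traits).
#' @param X covariate matrix without intercept (may have 0 columns); an
#'   intercept column is prepended.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @export
phenotype_table <- function(sample_ids, Y, X = NULL,
                            trait_type = c("binary", "quantitative")) {
  trait_type <- match.arg(trait_type)
  n <- length(Y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  stopifnot(length(sample_ids) == n, nrow(X) == n, !anyNA(Y))
  if (trait_type == "binary" && !all(Y %in% c(0, 1)))
    stop("binary trait must be coded 0/1")
  Xfull <- cbind(`(Intercept)` = 1, X)
  if (qr(Xfull)$rank < ncol(Xfull))
    stop("covariate matrix (with intercept) is rank deficient")
  structure(list(sample_ids = as.character(sample_ids),
                 Y = as.numeric(Y), X = Xfull, trait_type = trait_type),
            class = "phenotype_table")
}

#' Read a dosage table
#'
#' Simple TSV dialect for imputed dosages: columns `chrom`, `pos`, `id`, `a1`,
#' `a2`, then one column per sample (in genotype/fam order) holding expected
#' allele1 counts in \[0, 2\].
#'
#' @param path TSV path.
#' @return list with `variants` (a variant record table) and `dosages`
#'   (samples x variants numeric matrix with sample ids as rownames).
#' @export
read_dosage <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  need <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(need %in% names(tab)[1:5]))
    stop("dosage file must start with columns ", paste(need, collapse = ", "))
  samples <- names(tab)[-(1:5)]
  if (!length(samples)) stop("dosage file has no sample columns")
  D <- t(as.matrix(tab[, -(1:5), drop = FALSE]))
  if (any(D < 0 | D > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  rownames(D) <- samples
  variants <- data.frame(chrom = as.character(tab$chrom), pos = tab$pos,
                         id = tab$id, allele1 = tab$a1, allele2 = tab$a2)
  validate_variant_records(variants)
  list(variants = variants, dosages = D)
}

#' Read a trait manifest
#'
#' A manifest drives batched Step-2 runs: one row per trait naming the fitted
#' null-model file, the variance-ratio file and the output destination.
#'
#' @param path TSV with header `trait_id null_model variance_ratio output`.
#' @param check_paths verify that input files exist (default TRUE).
#' @return data.frame of class `trait_manifest`, rows in file order.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  tab <- data.table::fread(path, data.table = FALSE, colClasses = "character")
  need <- c("trait_id", "null_model", "variance_ratio", "output")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$trait_id))
    stop("duplicate trait_id in manifest: ",
         paste(unique(tab$trait_id[duplicated(tab$trait_id)]), collapse = ", "))
  if (check_paths && nrow(tab)) {
    for (p in c(tab$null_model, tab$variance_ratio))
      if (!file.exists(p)) stop("manifest input does not exist: ", p)
  }
  structure(tab[, need], class = c("trait_manifest", "data.frame"))
}

results_header <- c("CHR", "POS", "ID", "Allele1", "Allele2", "AF_Allele1",
                    "N", "BETA", "SE", "Tstat", "var", "p_value",
                    "p_value_NA", "is_SPA_converged")

#' Write an association-results table
#'
#' Fixed-header TSV, one row per variant in input order. P-values are written
#' in scientific notation and floored at the smallest positive double so a
#' zero is never printed.
#'
#' @param results data.frame as produced by [run_assoc()].
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  out <- data.frame(CHR = results$chrom, POS = results$pos, ID = results$id,
                    Allele1 = results$allele1, Allele2 = results$allele2,
                    AF_Allele1 = results$af, N = results$n,
                    BETA = results$beta, SE = results$se,
                    Tstat = results$Tstat, var = results$var,
                    p_value = pmax(results$p_value, .Machine$double.xmin),
                    p_value_NA = pmax(results$p_value_NA,
                                      .Machine$double.xmin),
                    is_SPA_converged = results$is_SPA_converged)
  num <- c("AF_Allele1", "BETA", "SE", "Tstat", "var", "p_value", "p_value_NA")
  for (cc in num) out[[cc]] <- formatC(out[[cc]], digits = 10, format = "g")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an association-results table written by [write_results()]
#' @param path TSV path.
#' @export
read_results <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  miss <- setdiff(results_header, names(tab))
  if (length(miss)) stop("results file lacks columns: ",
                         paste(miss, collapse = ", "))
  tab
}

#' Serialize a fitted null model
#'
#' Writes a self-describing JSON file holding everything Step 2 needs (fixed
#' effects, variance component, fitted means, weights, residuals, covariates,
#' sample ids), so association testing never re-fits the model. The format is
#' this package's own; it is not interoperable with other mixed-model GWAS
#' tools' binary model files.
#'
#' @param fit a `null_model_fit` from [fit_null_glmm()].
#' @param path output path.
#' @export
write_null_model <- function(fit, path) {
  obj <- list(format = "mmgwas_null_model", version = 1L,
              trait_type = fit$trait_type,
              alpha = unclass(fit$alpha), alpha_names = names(fit$alpha),
              tau = fit$tau, phi = fit$phi,
              mu = fit$mu, W = fit$W, residuals = fit$residuals,
              bhat = fit$bhat, X = as.vector(fit$X), p = ncol(fit$X),
              sample_ids = fit$sample_ids,
              variance_ratio = fit$variance_ratio,
              converged = fit$converged, n_iterations = fit$n_iterations)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized null model
#' @param path file written by [write_null_model()].
#' @export
read_null_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mmgwas_null_model"))
    stop("not an mmgwas null-model file: ", path)
  n <- length(obj$sample_ids)
  fit <- list(alpha = stats::setNames(obj$alpha, obj$alpha_names),
              tau = obj$tau, phi = obj$phi, mu = obj$mu, W = obj$W,
              residuals = obj$residuals, bhat = obj$bhat,
              X = matrix(obj$X, nrow = n, ncol = obj$p,
                         dimnames = list(NULL, obj$alpha_names)),
              sample_ids = obj$sample_ids, trait_type = obj$trait_type,
              variance_ratio = obj$variance_ratio,
              converged = obj$converged, n_iterations = obj$n_iterations)
  fit$Y <- fit$residuals + fit$mu
  if (fit$trait_type == "binary") fit$Y <- round(fit$Y)
  class(fit) <- "null_model_fit"
  fit
}

#' Write / read a variance-ratio file
#'
#' One calibration scalar per trait, stored as a tiny JSON object.
#' @param r positive scalar variance ratio.
#' @param path file path.
#' @export
write_variance_ratio <- function(r, path) {
  stopifnot(is.finite(r), r > 0)
  jsonlite::write_json(list(variance_ratio = r), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_variance_ratio
#' @export
read_variance_ratio <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- obj$variance_ratio
  if (is.null(r) || !is.finite(r) || r <= 0)
    stop("not a valid variance-ratio file: ", path)
  r
}
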