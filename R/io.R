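#' Write a patch bag to disk
#'
#' Stores the bag as a TSV pair — `<stem>_features.tsv` (K x D, no
#' header) and `<stem>_coords.tsv` (K x 2, header `x`, `y`) — plus a
#' sidecar `<stem>_meta.json` holding `slide_id`, `patch_size` and
#' `extractor_id`.
#'
#' @param bag A [patch_bag].
#' @param stem Path stem (directory + basename without suffix).
#' @return The stem, invisibly.
#' @export
write_bag <- function(bag, stem) {
  stopifnot(inherits(bag, "patch_bag"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bag$features, paste0(stem, "_features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(bag$coords, paste0(stem, "_coords.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(list(slide_id = bag$slide_id,
                            patch_size = bag$patch_size,
                            extractor_id = bag$extractor_id),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read a patch bag written by [write_bag()]
#'
#' @param stem Path stem used at write time.
#' @return A [patch_bag].
#' @export
read_bag <- function(stem) {
  feats <- as.matrix(utils::read.table(paste0(stem, "_features.tsv"),
                                       sep = "\t"))
  dimnames(feats) <- NULL
  coords <- as.matrix(utils::read.table(paste0(stem, "_coords.tsv"),
                                        sep = "\t", header = TRUE))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  patch_bag(meta$slide_id, feats, coords,
            extractor_id = meta$extractor_id,
            patch_size = meta$patch_size)
}

#' Write a synthetic cohort to a directory
#'
#' Layout: `patients.csv` (patient_id, time_months, event),
#' `expression.tsv` (genes x patients, gene ids as first column),
#' `clinical.csv`, `bags/<patient_id>_*.tsv`, `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "bags"), recursive = TRUE, showWarnings = FALSE)
  pat <- data.frame(patient_id = cohort$patients$patient_id,
                    time_months = cohort$patients$time,
                    event = cohort$patients$event)
  utils::write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE)
  expr <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(patient_id = rownames(cohort$clinical),
                              cohort$clinical, check.names = FALSE),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  for (i in seq_along(cohort$bags)) {
    write_bag(cohort$bags[[i]],
              file.path(dir, "bags", cohort$patients$patient_id[i]))
  }
  jsonlite::write_json(
    list(eta = cohort$truth$eta,
         image_fraction = cohort$truth$image_fraction,
         gene_aggregate = cohort$truth$gene_aggregate,
         clinical_score = cohort$truth$clinical_score,
         planted_genes = cohort$truth$planted_genes,
         signal_idx = cohort$truth$signal_idx),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A cohort-like list usable by [milcox()] (without the
#'   generator's full truth record unless `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"))
  patients <- surv_data(pat$time_months, pat$event, pat$patient_id)
  expr_df <- utils::read.table(file.path(dir, "expression.tsv"), sep = "\t",
                               header = TRUE, check.names = FALSE)
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$gene
  clin_df <- utils::read.csv(file.path(dir, "clinical.csv"),
                             check.names = FALSE)
  clinical <- as.matrix(clin_df[, -1, drop = FALSE])
  rownames(clinical) <- clin_df$patient_id
  bags <- lapply(patients$patient_id, function(id) {
    read_bag(file.path(dir, "bags", id))
  })
  out <- list(patients = patients, bags = bags, expression = expression,
              clinical = clinical)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  }
  out
}

#' Save a fitted model to a single-file archive
#'
#' Serializes parameters and config as JSON (text, portable across
#' platforms); numeric precision is preserved via full digits.
#'
#' @param object A fitted [milcox].
#' @param path Output path (conventionally `.milcox.json`).
#' @return `path`, invisibly.
#' @export
save_milcox <- function(object, path) {
  stopifnot(inherits(object, "milcox"))
  par <- lapply(object$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = NULL, data = as.numeric(p))
  })
  payload <- list(params = par, dims = object$dims,
                  config = unclass(object$config),
                  gene_panel = object$gene_panel,
                  standardize = object$standardize)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_milcox()]
#'
#' @param path Archive path.
#' @return A [milcox] object (without training history).
#' @export
load_milcox <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else as.numeric(p$data)
  })
  dims <- as.list(payload$dims)
  attr(par, "dims") <- dims
  std <- payload$standardize
  out <- list(params = par, dims = dims,
              config = do.call(milcox_config,
                               payload$config[names(payload$config) %in%
                                                names(formals(milcox_config))]),
              gene_panel = payload$gene_panel,
              standardize = lapply(std, unlist))
  class(out) <- "milcox"
  out
}
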