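# Readers and writers for the pipeline's artifacts. All round-trips are
# lossless at documented tolerances: vertices to 1e-6 px (CSV/JSON store full
# precision), feature and clinical tables exactly, model bundles bit-for-bit
# in their predictions.

#' Read / write nuclear boundaries
#'
#' CSV dialect: columns `spot_id,nucleus_id,vertex_index,x,y`, preceded by a
#' comment line `# image_size: <w> <h>`. JSON dialect: an object with
#' `spot_id`, `image_size` and a `nuclei` array of `{nucleus_id, vertices}`.
#' Malformed polygons (fewer than 8 vertices, self-intersecting, zero area)
#' are rejected with an error naming the offending nucleus.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return A [nuclei_set()].
#' @export
read_nuclei <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    nuclei <- lapply(j$nuclei, function(nu) {
      v <- do.call(rbind, lapply(nu$vertices, function(p) c(p[[1]], p[[2]])))
      nucleus_boundary(nu$nucleus_id, v)
    })
    return(nuclei_set(j$spot_id, nuclei, unlist(j$image_size)))
  }
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*image_size:", first)) {
    stop("CSV nuclei file must start with a '# image_size: <w> <h>' line")
  }
  size <- as.integer(strsplit(sub("^#\\s*image_size:\\s*", "", first), "\\s+")[[1]])
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  need <- c("spot_id", "nucleus_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop("nuclei CSV missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  ids <- unique(df$nucleus_id)
  nuclei <- lapply(ids, function(id) {
    sub <- df[df$nucleus_id == id, ]
    sub <- sub[order(sub$vertex_index), ]
    nucleus_boundary(id, cbind(sub$x, sub$y))
  })
  nuclei_set(df$spot_id[1], nuclei, size)
}

#' @rdname read_nuclei
#' @param ns A [nuclei_set()] to write.
#' @export
write_nuclei <- function(ns, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(ns, "nuclei_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    j <- list(spot_id = ns$spot_id, image_size = ns$image_size,
              nuclei = lapply(ns$nuclei, function(nu) {
                list(nucleus_id = nu$nucleus_id,
                     vertices = lapply(seq_len(nrow(nu$vertices)),
                                       function(i) nu$vertices[i, ]))
              }))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(ns$nuclei, function(nu) {
      data.frame(spot_id = ns$spot_id, nucleus_id = nu$nucleus_id,
                 vertex_index = seq_len(nrow(nu$vertices)) - 1L,
                 x = nu$vertices[, 1], y = nu$vertices[, 2],
                 stringsAsFactors = FALSE)
    }))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# image_size: %d %d", ns$image_size[1], ns$image_size[2]), con)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write a feature table
#'
#' CSV with a `spot_id` column followed by the 242 registry columns in
#' registry order. Reading validates the header strictly: unknown feature
#' columns are an error, missing ones are reported by name.
#'
#' @param path File path.
#' @return Data.frame `spot_id` + 242 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  reg <- feature_registry()
  cols <- setdiff(names(df), "spot_id")
  unknown <- setdiff(cols, reg$name)
  if (length(unknown)) stop("unknown feature column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(reg$name, cols)
  if (length(missing)) stop("missing: ", paste(missing, collapse = ", "))
  if (!"spot_id" %in% names(df)) stop("missing: spot_id")
  df[, c("spot_id", reg$name)]
}

#' @rdname read_feature_table
#' @param df Feature data.frame to write.
#' @export
write_feature_table <- function(df, path) {
  reg <- feature_registry()
  missing <- setdiff(reg$name, names(df))
  if (length(missing)) stop("missing: ", paste(missing, collapse = ", "))
  utils::write.csv(df[, c("spot_id", reg$name)], path, row.names = FALSE)
  invisible(path)
}

clinical_fields <- c("patient_id", "batch", "gender", "t_stage", "n_stage",
                     "stage", "recurrence", "rfs_months", "event_observed")

#' Read / write a clinical table
#'
#' One row per patient-batch. Fields: patient_id, batch, gender (M/F), t_stage
#' (T1/T2), n_stage (N0/N1), stage (I/II), recurrence (logical), rfs_months
#' (non-negative), event_observed (logical).
#'
#' @param path File path.
#' @return Data.frame with the documented schema.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(clinical_fields, names(df))
  if (length(missing)) {
    stop("clinical table missing field(s): ", paste(missing, collapse = ", "))
  }
  df$recurrence <- as.logical(df$recurrence)
  df$event_observed <- as.logical(df$event_observed)
  if (any(df$rfs_months < 0)) stop("rfs_months must be non-negative")
  bad <- !df$gender %in% c("M", "F")
  if (any(bad)) stop("invalid gender for: ", paste(df$patient_id[bad], collapse = ", "))
  df[, clinical_fields]
}

#' @rdname read_clinical
#' @param df Clinical data.frame to write.
#' @export
write_clinical <- function(df, path) {
  missing <- setdiff(clinical_fields, names(df))
  if (length(missing)) {
    stop("clinical table missing field(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(df[, clinical_fields], path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted classifier bundle
#'
#' JSON serialization at full double precision; a reloaded bundle reproduces
#' predictions bit-for-bit.
#'
#' @param model A `recurrence_classifier` object.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "recurrence_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @return For `load_model`, the restored `recurrence_classifier`.
#' @export
load_model <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  j$selected <- as.character(j$selected)
  j$means <- unlist(j$means); j$sds <- unlist(j$sds)
  names(j$means) <- j$selected; names(j$sds) <- j$selected
  if (j$kind %in% c("QDA", "LDA")) {
    j$fit$mean0 <- as.numeric(j$fit$mean0)
    j$fit$mean1 <- as.numeric(j$fit$mean1)
    j$fit$cov0 <- as.matrix(j$fit$cov0)
    j$fit$cov1 <- as.matrix(j$fit$cov1)
  } else {
    j$fit$sv <- as.matrix(j$fit$sv)
    j$fit$coefs <- as.numeric(j$fit$coefs)
  }
  class(j) <- "recurrence_classifier"
  j
}
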