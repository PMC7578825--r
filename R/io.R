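#' Construct a per-individual diet matrix
#'
#' A diet matrix holds one row per (individual, prey taxon) with the number of
#' items counted and/or the wet mass recovered from the foregut. Either
#' `count` or `mass` may be missing on a row; the record then simply does not
#' contribute to metrics that need the missing field. Duplicate
#' (individual, taxon) rows are summed.
#'
#' @param df data frame with columns `individual_id`, `group`, `prey_taxon`,
#'   `count` (non-negative integers, NA allowed) and `mass` (non-negative
#'   grams, NA allowed).
#' @return A `diet_matrix`, a validated data frame with group levels ordered
#'   by first appearance.
#' @export
diet_matrix <- function(df) {
  req <- c("individual_id", "group", "prey_taxon", "count", "mass")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_validation("diet table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$count <- as.numeric(df$count)
  df$mass <- as.numeric(df$mass)
  bad <- which(!is.na(df$count) & (df$count < 0 | df$count != round(df$count)))
  if (length(bad)) {
    stop_validation("column `count` must hold non-negative integers; offending row(s): %s",
                    paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(df$mass) & (df$mass < 0 | !is.finite(df$mass)))
  if (length(bad)) {
    stop_validation("column `mass` must hold finite non-negative values; offending row(s): %s",
                    paste(bad, collapse = ", "))
  }
  df$group <- appearance_factor(df$group)
  df$individual_id <- as.character(df$individual_id)
  df$prey_taxon <- as.character(df$prey_taxon)
  # collapse duplicate (individual, taxon) records
  key <- paste(df$individual_id, df$prey_taxon, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    sp <- split(seq_len(nrow(df)), key)
    df <- do.call(rbind, lapply(sp, function(idx) {
      r <- df[idx[1L], , drop = FALSE]
      r$count <- agg(df$count[idx])
      r$mass <- agg(df$mass[idx])
      r
    }))
    df <- df[order(match(df$individual_id, unique(df$individual_id))), ]
    rownames(df) <- NULL
  }
  structure(df, class = c("diet_matrix", "data.frame"))
}

#' Read a diet-composition CSV
#'
#' @param path CSV with header `individual_id,group,prey_taxon,count,mass`.
#' @return A [diet_matrix()].
#' @export
read_diet_csv <- function(path) {
  diet_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Construct a per-sample stable-isotope table
#'
#' @param df data frame with columns `sample_id`, `group`, `d13C`, `d15N`
#'   (per-mil) and optionally `SL` (standard length, mm; NA allowed).
#' @return An `isotope_table` data frame.
#' @export
isotope_table <- function(df) {
  req <- c("sample_id", "group", "d13C", "d15N")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_validation("isotope table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)
  if (!"SL" %in% names(df)) df$SL <- NA_real_
  df <- df[c(req, "SL")]
  for (col in c("d13C", "d15N")) {
    bad <- which(!is.finite(as.numeric(df[[col]])))
    if (length(bad)) {
      stop_validation("column `%s` must be finite; offending row(s): %s",
                      col, paste(bad, collapse = ", "))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df$SL <- as.numeric(df$SL)
  bad <- which(!is.na(df$SL) & df$SL <= 0)
  if (length(bad)) {
    stop_validation("column `SL` must be positive; offending row(s): %s",
                    paste(bad, collapse = ", "))
  }
  df$group <- appearance_factor(df$group)
  df$sample_id <- as.character(df$sample_id)
  structure(df, class = c("isotope_table", "data.frame"))
}

#' @rdname isotope_table
#' @param path CSV with header `sample_id,group,d13C,d15N[,SL]`.
#' @export
read_isotope_csv <- function(path) {
  isotope_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Construct a prey-source signature set for mixing models
#'
#' Each source carries a mean and SD per tracer plus the trophic enrichment
#' factor (TEF) mean and SD applied to it. A TEF is the isotopic offset
#' between consumer tissue and diet.
#'
#' @param df data frame with columns `source`, `d13C_mean`, `d13C_sd`,
#'   `d15N_mean`, `d15N_sd`, `tef_d13C_mean`, `tef_d13C_sd`, `tef_d15N_mean`,
#'   `tef_d15N_sd`.
#' @return A `source_set` data frame.
#' @export
source_set <- function(df) {
  req <- c("source", "d13C_mean", "d13C_sd", "d15N_mean", "d15N_sd",
           "tef_d13C_mean", "tef_d13C_sd", "tef_d15N_mean", "tef_d15N_sd")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_validation("source table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  if (nrow(df) < 1L) stop_validation("source table needs at least one source")
  if (anyDuplicated(df$source)) stop_validation("duplicate source names")
  for (col in req[-1]) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop_validation("column `%s` must be finite; offending row(s): %s",
                      col, paste(bad, collapse = ", "))
    }
  }
  for (col in grep("_sd$", req, value = TRUE)) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop_validation("column `%s` must be >= 0; offending row(s): %s",
                      col, paste(bad, collapse = ", "))
    }
  }
  df$source <- as.character(df$source)
  structure(df, class = c("source_set", "data.frame"))
}

#' @rdname source_set
#' @param path CSV path.
#' @export
read_sources_csv <- function(path) {
  source_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Construct a gut-fullness observation table
#'
#' Fullness (`ff`) is scored visually on an ordinal 0-5 scale (0 = empty
#' intestine, 1 = 1/4 full, ..., 4 = full, 5 = distended). `Wt`, `Wgut`, `Wg`
#' are body, gut and gonad wet masses in grams.
#'
#' @param df data frame with columns `individual_id`, `group`, `season`,
#'   `time_h`, `ff`, `Wt`, `Wgut`, `Wg`.
#' @return A `fullness_table` data frame.
#' @export
fullness_table <- function(df) {
  req <- c("individual_id", "group", "season", "time_h", "ff", "Wt", "Wgut", "Wg")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_validation("fullness table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$ff <- as.numeric(df$ff)
  bad <- which(!(df$ff %in% 0:5))
  if (length(bad)) {
    stop_validation("column `ff` must be an integer in 0..5; offending row(s): %s",
                    paste(bad, collapse = ", "))
  }
  for (col in c("Wt", "Wgut", "Wg")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop_validation("column `%s` must be positive; offending row(s): %s",
                      col, paste(bad, collapse = ", "))
    }
  }
  bad <- which(df$Wgut > df$Wt | df$Wg > df$Wt)
  if (length(bad)) {
    stop_validation("`Wgut` and `Wg` cannot exceed `Wt`; offending row(s): %s",
                    paste(bad, collapse = ", "))
  }
  df$group <- appearance_factor(df$group)
  df$season <- appearance_factor(df$season)
  df$time_h <- appearance_factor(df$time_h)
  structure(df, class = c("fullness_table", "data.frame"))
}

#' @rdname fullness_table
#' @param path CSV path.
#' @export
read_fullness_csv <- function(path) {
  fullness_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---- result serialization -------------------------------------------------

result_classes <- c("niche_metrics", "specialization_result", "mix_result",
                    "test_result", "regression_fit", "overlap_matrix",
                    "ellipse_overlap", "lmm_fit")

as_result_list <- function(x) {
  cls <- intersect(class(x), result_classes)[1]
  if (inherits(x, "overlap_matrix")) {
    out <- list(groups = colnames(x), values = unclass(x))
  } else if (inherits(x, "mix_result")) {
    out <- list(sources = x$sources, diagnostics = x$diagnostics)
  } else if (inherits(x, "lmm_fit")) {
    out <- x[c("formula_tag", "fixef", "season_sd", "residual_sd", "logLik", "n_fixef")]
  } else {
    out <- lapply(unclass(x), function(v) if (is.factor(v)) as.character(v) else v)
    out <- out[!vapply(out, is.function, logical(1))]
    out$model <- NULL   # drop fitted-model payloads, keep scalar fields
  }
  c(list(.class = cls), out)
}

#' Write a pipeline result to CSV or JSON
#'
#' JSON output embeds the result class so that [read_results()] can
#' reconstruct the object; values are written at full precision so the
#' round trip is lossless.
#'
#' @param x a result object (`niche_metrics`, `specialization_result`,
#'   `mix_result`, `test_result`, `regression_fit`, `overlap_matrix`, ...).
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @export
write_results <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  lst <- as_result_list(x)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    if (inherits(x, "overlap_matrix")) {
      utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
    } else if (inherits(x, "mix_result")) {
      utils::write.csv(x$sources, path, row.names = FALSE)
    } else {
      flat <- lst[vapply(lst, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
      utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read back a JSON result written by [write_results()]
#'
#' @param path JSON file path.
#' @return The result object with its original class restored.
#' @export
read_results <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cls <- lst$.class
  lst$.class <- NULL
  if (identical(cls, "overlap_matrix")) {
    m <- as.matrix(lst$values)
    dimnames(m) <- list(lst$groups, lst$groups)
    return(structure(m, class = c("overlap_matrix", "matrix")))
  }
  if (identical(cls, "mix_result")) {
    return(structure(list(sources = as.data.frame(lst$sources),
                          diagnostics = lst$diagnostics),
                     class = "mix_result"))
  }
  structure(lst, class = cls)
}
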