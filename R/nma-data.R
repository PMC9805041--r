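#' Validate an arm-level network meta-analysis table
#'
#' Checks and normalises a long-format table of arm-level binary outcome data
#' (one row per study arm) for use by the fitting functions. Studies are kept
#' in order of first appearance and arms in their original row order, so the
#' design matrix built from the result is reproducible.
#'
#' @param x A data frame with columns `study`, `treatment`, `events`, `n`
#'   (character/factor labels for the first two, non-negative counts for
#'   `events`, positive counts for `n`).
#' @return A tibble of class `nma_data` with columns `study`, `treatment`,
#'   `events`, `n`.
#' @details Validation enforces: `0 <= events <= n` per arm, at least two arms
#'   per study, no duplicated treatment within a study, and at least two
#'   distinct treatments overall. All-zero-event studies are legitimate data
#'   and are retained; use [drop_all_zero_studies()] to exclude them.
#' @examples
#' arms <- tibble::tibble(
#'   study = c("s1", "s1", "s2", "s2"),
#'   treatment = c("A", "B", "A", "C"),
#'   events = c(0L, 1L, 2L, 0L),
#'   n = c(10L, 10L, 50L, 50L)
#' )
#' nma_data(arms)
#' @export
nma_data <- function(x) {
  x <- as.data.frame(x)
  required <- c("study", "treatment", "events", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    study = as.character(x$study),
    treatment = as.character(x$treatment),
    events = as.integer(x$events),
    n = as.integer(x$n)
  )
  if (anyNA(out)) stop("missing values in study/treatment/events/n", call. = FALSE)
  if (any(out$n <= 0)) {
    stop("non-positive sample size in row(s) ",
         paste(which(out$n <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(out$events < 0)) {
    stop("negative event count in row(s) ",
         paste(which(out$events < 0), collapse = ", "), call. = FALSE)
  }
  bad <- which(out$events > out$n)
  if (length(bad) > 0) {
    stop("events exceed sample size in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # preserve first-appearance study order and file row order within study
  out$study <- factor(out$study, levels = unique(out$study))
  out <- out[order(as.integer(out$study)), , drop = FALSE]
  out$study <- as.character(out$study)

  arm_counts <- table(out$study)
  singles <- names(arm_counts)[arm_counts < 2]
  if (length(singles) > 0) {
    stop("single-arm study: ", paste(singles, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(out[, c("study", "treatment")])
  if (any(dup)) {
    key <- paste0(out$study[dup], "/", out$treatment[dup])
    stop("duplicated (study, treatment) pair: ",
         paste(unique(key), collapse = ", "), call. = FALSE)
  }
  if (length(unique(out$treatment)) < 2) {
    stop("need at least two distinct treatments", call. = FALSE)
  }
  class(out) <- c("nma_data", class(out))
  out
}

#' Read arm-level network data from a delimited file
#'
#' Reads a long-format CSV/TSV file (one row per study arm) and validates it
#' with [nma_data()]. Columns named differently from the canonical
#' `study`/`treatment`/`events`/`n` can be renamed via `column_map`, supplied
#' either as a named list/vector (`canonical = file_column`) or as the path to
#' a YAML file holding such a mapping.
#'
#' @param path Path to a CSV (or TSV; the delimiter is sniffed from the
#'   extension) file.
#' @param column_map Optional named list/character vector or YAML file path
#'   mapping canonical names to the file's column names.
#' @return An `nma_data` tibble.
#' @export
read_nma <- function(path, column_map = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    if (is.character(column_map) && length(column_map) == 1 &&
        file.exists(column_map)) {
      column_map <- yaml::read_yaml(column_map)
    }
    column_map <- unlist(column_map)
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(raw)) {
        stop("column '", src, "' (mapped to '", canonical,
             "') not found in file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  nma_data(raw)
}

#' Write arm-level network data to CSV
#'
#' @param data An `nma_data` tibble (or coercible data frame).
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_nma <- function(data, path) {
  data <- nma_data(data)
  readr::write_csv(tibble::as_tibble(unclass(data)), path, progress = FALSE)
  invisible(data)
}

#' Drop studies with zero events in every arm
#'
#' The penalized-likelihood model retains all-zero-event studies by default;
#' this helper supports sensitivity analyses that exclude them, as classical
#' methods must.
#'
#' @param data An `nma_data` tibble.
#' @return An `nma_data` tibble without the all-zero-event studies; the
#'   dropped study ids are stored in attribute `"dropped"`.
#' @export
drop_all_zero_studies <- function(data) {
  data <- nma_data(data)
  totals <- tapply(data$events, factor(data$study, levels = unique(data$study)), sum)
  drop <- names(totals)[totals == 0]
  out <- nma_data(data[!data$study %in% drop, , drop = FALSE])
  attr(out, "dropped") <- drop
  out
}

#' Treatment-network connectivity
#'
#' Builds the comparison graph (treatments as nodes, an edge for every
#' within-study treatment pair) and reports its connected components in
#' sorted order. Zero-event arms still contribute edges: the penalized
#' likelihood keeps such studies informative, so excluding them is exactly
#' what can disconnect a network.
#'
#' @param data An `nma_data` tibble.
#' @return A list with elements `connected` (logical) and `components`
#'   (list of sorted character vectors of treatment labels, sorted by first
#'   element).
#' @export
nma_connectivity <- function(data) {
  if (!inherits(data, "nma_data")) data <- nma_data(data)
  pair_mat <- do.call(cbind, lapply(
    split(data$treatment, factor(data$study, levels = unique(data$study))),
    function(trt) utils::combn(sort(trt), 2)
  ))
  edges <- unique(data.frame(V1 = pair_mat[1, ], V2 = pair_mat[2, ]))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = sort(unique(data$treatment))
  )
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[[`, "", 1))]
  names(members) <- NULL
  list(connected = comp$no == 1L, components = members)
}

#' Design matrix for the logistic NMA model
#'
#' Builds the 0/1 design matrix `Z` with one row per study arm: `N` study
#' intercept columns followed by `T - 1` treatment columns under a single
#' global reference, so treatment column `t` encodes the basic parameter
#' d(reference -> t). Reference-treatment arms have an all-zero treatment
#' block. The dimensions are (total arms) x (N + T - 1), and `Z` has full
#' column rank exactly when the network is connected.
#'
#' @param data An `nma_data` tibble.
#' @param reference Reference treatment label; defaults to the
#'   lexicographically smallest label.
#' @return A list of class `nma_design`: `Z` (matrix), `row_index` (tibble of
#'   study/treatment per row), `col_labels`, `reference`, `studies`,
#'   `treatments` (reference first).
#' @export
nma_design <- function(data, reference = NULL) {
  if (!inherits(data, "nma_data")) data <- nma_data(data)
  treatments <- sort(unique(data$treatment))
  if (is.null(reference)) reference <- treatments[1]
  if (!reference %in% treatments) {
    stop("unknown reference treatment: ", reference, call. = FALSE)
  }
  conn <- nma_connectivity(data)
  if (!conn$connected) {
    stop("disconnected network; components: ",
         paste(vapply(conn$components, paste, "", collapse = "+"),
               collapse = " | "), call. = FALSE)
  }
  studies <- unique(data$study)
  non_ref <- setdiff(treatments, reference)
  n_arm <- nrow(data)
  Z <- matrix(0, nrow = n_arm, ncol = length(studies) + length(non_ref))
  study_idx <- match(data$study, studies)
  Z[cbind(seq_len(n_arm), study_idx)] <- 1
  trt_idx <- match(data$treatment, non_ref)  # NA for reference arms
  has_trt <- !is.na(trt_idx)
  Z[cbind(which(has_trt), length(studies) + trt_idx[has_trt])] <- 1
  col_labels <- c(paste0("alpha[", studies, "]"),
                  paste0("d[", reference, ":", non_ref, "]"))
  colnames(Z) <- col_labels
  structure(
    list(
      Z = Z,
      row_index = tibble::tibble(study = data$study, treatment = data$treatment),
      col_labels = col_labels,
      reference = reference,
      studies = studies,
      treatments = c(reference, non_ref)
    ),
    class = "nma_design"
  )
}

#' @export
print.nma_data <- function(x, ...) {
  cat("<nma_data> ", length(unique(x$study)), " studies, ",
      length(unique(x$treatment)), " treatments, ", nrow(x), " arms\n",
      sep = "")
  NextMethod()
}
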