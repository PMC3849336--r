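SCHEMA_VERSION <- "1.0"

#' Read a case-control dataset from delimited text
#'
#' CSV or TSV with a header row; the delimiter is inferred from the header
#' line (tab wins over comma).  One column is the binary outcome; every
#' other numeric column becomes a feature, in file order.
#'
#' @param path file path.
#' @param outcome_column name of the outcome column (default `"outcome"`).
#' @param drop_columns character vector of column names to exclude.
#' @return a [case_control_dataset()].
#' @export
read_dataset <- function(path, outcome_column = "outcome",
                         drop_columns = character()) {
  if (!file.exists(path)) {
    synet_error("synet_io_error", sprintf("file not found: %s", path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!outcome_column %in% names(df)) {
    synet_error("synet_input_error",
                sprintf("outcome column '%s' not found (columns: %s)",
                        outcome_column, paste(names(df), collapse = ", ")))
  }
  y <- df[[outcome_column]]
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad)) {
    synet_error("synet_input_error",
                sprintf("outcome column '%s' contains '%s' at row %d; only 0/1 allowed",
                        outcome_column, as.character(y[bad[1L]]), bad[1L]))
  }
  feats <- df[, setdiff(names(df), c(outcome_column, drop_columns)),
              drop = FALSE]
  for (cn in names(feats)) {
    col <- feats[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      synet_error("synet_input_error",
                  sprintf("non-numeric value '%s' in feature column '%s' (row %d)",
                          as.character(col[bad]), cn, bad))
    }
    if (anyNA(col)) {
      synet_error("synet_input_error",
                  sprintf("missing value in feature column '%s' (row %d)",
                          cn, which(is.na(col))[1L]))
    }
  }
  case_control_dataset(as.matrix(feats), y, names(feats))
}

#' Write a case-control dataset as CSV
#'
#' Features plus an `outcome` column, serialized with 17 significant digits
#' so a write-then-read round trip reproduces the matrix bit-exactly.
#'
#' @param dataset a [case_control_dataset()].
#' @param path destination path.
#' @param outcome_column name for the outcome column.
#' @export
write_dataset <- function(dataset, path, outcome_column = "outcome") {
  m <- dataset$features
  txt <- vapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]),
                character(nrow(m)))
  if (nrow(m) == 1L) txt <- matrix(txt, nrow = 1L)
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- dataset$feature_names
  df[[outcome_column]] <- dataset$outcome
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synergy network as edge/node weight tables
#'
#' Edge list TSV (`node_a  node_b  weight`, one row per unordered pair) and
#' node weight TSV (`node  weight`).
#'
#' @param network a `synergy_network`.
#' @param edge_path,node_path destination paths (either may be `NULL`).
#' @export
write_network <- function(network, edge_path = NULL, node_path = NULL) {
  if (!is.null(edge_path)) {
    ut <- which(upper.tri(network$edge_weights), arr.ind = TRUE)
    df <- data.frame(node_a = network$feature_names[ut[, 1L]],
                     node_b = network$feature_names[ut[, 2L]],
                     weight = network$edge_weights[ut])
    utils::write.table(df, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(node_path)) {
    df <- data.frame(node = network$feature_names,
                     weight = as.numeric(network$node_weights))
    utils::write.table(df, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(network)
}

#' Export a synergy network as GraphML
#'
#' Nodes carry the individual power as attribute `f`; edges carry the
#' synergistic power as attribute `s`.
#'
#' @param network a `synergy_network`.
#' @param path destination path.
#' @export
write_graphml <- function(network, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "f", `for` = "node",
                      attr.name = "f", attr.type = "double")
  xml2::xml_add_child(doc, "key", id = "s", `for` = "edge",
                      attr.name = "s", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "synergy_network",
                           edgedefault = "undirected")
  for (i in seq_along(network$feature_names)) {
    nd <- xml2::xml_add_child(g, "node", id = network$feature_names[i])
    dt <- xml2::xml_add_child(nd, "data", key = "f")
    xml2::xml_text(dt) <- sprintf("%.17g", network$node_weights[i])
  }
  ut <- which(upper.tri(network$edge_weights), arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = network$feature_names[ut[k, 1L]],
                              target = network$feature_names[ut[k, 2L]])
    dt <- xml2::xml_add_child(ed, "data", key = "s")
    xml2::xml_text(dt) <- sprintf("%.17g", network$edge_weights[ut[k, 1L],
                                                                ut[k, 2L]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a feature ranking
#'
#' TSV with columns `rank`, `feature`, `score`, `node_weight`; the JSON
#' variant adds the leading eigenvalue and fallback flag.
#'
#' @param ranking a `feature_ranking`.
#' @param path destination TSV path.
#' @param json_path optional JSON path.
#' @export
write_ranking <- function(ranking, path, json_path = NULL) {
  ord <- ranking$order
  df <- data.frame(rank = seq_along(ord),
                   feature = ranking$feature_names[ord],
                   score = as.numeric(ranking$scores[ord]),
                   node_weight = as.numeric(ranking$node_weights[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- list(schema_version = SCHEMA_VERSION,
                method = ranking$method,
                eigenvalue = if (is.null(ranking$eigenvalue)) NULL else ranking$eigenvalue,
                diagonal_fallback_used = isTRUE(ranking$diagonal_fallback_used),
                unstable = isTRUE(ranking$unstable),
                ranking = df)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Serialize an evaluation report to JSON
#'
#' Carries the full configuration and seed block so any run can be
#' reproduced, plus per-fold records, selected subsets, selection
#' frequencies and the consensus set.
#'
#' @param report an `evaluation_report`.
#' @param path destination JSON path.
#' @export
write_report <- function(report, path) {
  obj <- list(
    schema_version = SCHEMA_VERSION,
    config = list(ranking_method = report$ranking_method,
                  metric = report$metric, lambda = report$lambda,
                  n_repeats = report$n_repeats, n_folds = report$n_folds,
                  inner_folds = report$inner_folds, seed = report$seed,
                  consensus_threshold = report$consensus_threshold),
    feature_names = report$feature_names,
    records = report$records,
    subsets = lapply(report$subsets, as.integer),
    selection_frequency = as.list(report$selection_frequency),
    consensus = as.integer(report$consensus),
    aggregates = list(mean_accuracy = report$mean_accuracy,
                      sd_accuracy = report$sd_accuracy,
                      mean_auc = report$mean_auc,
                      sd_auc = report$sd_auc),
    n_empty_selections = report$n_empty_selections,
    n_skipped_inner_folds = report$n_skipped_inner_folds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path JSON path written by [write_report()].
#' @return an `evaluation_report` (without per-fold networks).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- unlist(obj$selection_frequency)
  subsets <- obj$subsets
  if (is.list(subsets)) subsets <- lapply(subsets, as.integer)
  else subsets <- apply(subsets, 1L, as.integer, simplify = FALSE)
  structure(list(
    ranking_method = obj$config$ranking_method, metric = obj$config$metric,
    lambda = obj$config$lambda, n_repeats = obj$config$n_repeats,
    n_folds = obj$config$n_folds, inner_folds = obj$config$inner_folds,
    seed = obj$config$seed,
    consensus_threshold = obj$config$consensus_threshold,
    feature_names = obj$feature_names,
    records = as.data.frame(obj$records),
    subsets = subsets,
    selection_frequency = stats::setNames(as.numeric(freq), obj$feature_names),
    consensus = stats::setNames(as.integer(obj$consensus),
                                obj$feature_names[as.integer(obj$consensus)]),
    mean_accuracy = obj$aggregates$mean_accuracy,
    sd_accuracy = obj$aggregates$sd_accuracy,
    mean_auc = obj$aggregates$mean_auc,
    sd_auc = obj$aggregates$sd_auc,
    n_empty_selections = obj$n_empty_selections,
    n_skipped_inner_folds = obj$n_skipped_inner_folds,
    networks = NULL),
    class = "evaluation_report")
}
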