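#' Semantic-triple triangulation
#'
#' Literature-derived subject-predicate-object triples provide an
#' evidence stream independent of the genetic one: when an object of a
#' triple from the exposure query matches a subject of a triple from the
#' outcome query, the shared term is a candidate intermediate linking
#' exposure to outcome (e.g. glycine - INTERACTS_WITH - homocysteine;
#' homocysteine - PREDISPOSES - coronary arteriosclerosis). Matching is
#' case-insensitive exact string equality after whitespace
#' normalization; no stemming or ontology mapping is attempted, since
#' fuzzy matching would silently change overlap sets.
#'
#' @name triples
NULL

normalize_term <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Read a semantic-triple table
#'
#' @param path delimited file with columns `subject`, `predicate`,
#'   `object` and optionally `local_count`, `local_total`,
#'   `global_count`, `global_total` (enrichment counts).
#' @return data.frame of triples; missing count columns are filled with
#'   `NA`.
#' @export
read_triples <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  req <- c("subject", "predicate", "object")
  if (!all(req %in% names(df))) {
    stop_config("triple table needs columns: ", paste(req, collapse = ", "))
  }
  for (col in c("local_count", "local_total", "global_count", "global_total")) {
    if (is.null(df[[col]])) df[[col]] <- NA_integer_
  }
  df
}

#' Fisher enrichment p-value for a triple
#'
#' One-sided Fisher exact test for over-representation of the triple in
#' the query's local literature set against the global background:
#' 2x2 table `[[local_count, local_total - local_count],
#' [global_count, global_total - global_count]]`, alternative
#' "greater". Vectorized over the four count arguments.
#'
#' @param local_count,local_total,global_count,global_total
#'   non-negative integers with `local_count <= local_total` and
#'   `global_count <= global_total`.
#' @return numeric vector of p-values; `NA` where any count is missing.
#' @export
triple_enrichment <- function(local_count, local_total, global_count,
                              global_total) {
  n <- max(length(local_count), length(local_total), length(global_count),
           length(global_total))
  lc <- rep_len(local_count, n); lt <- rep_len(local_total, n)
  gc <- rep_len(global_count, n); gt <- rep_len(global_total, n)
  vapply(seq_len(n), function(i) {
    if (anyNA(c(lc[i], lt[i], gc[i], gt[i]))) return(NA_real_)
    if (lc[i] > lt[i] || gc[i] > gt[i]) {
      stop_param("counts must satisfy local_count <= local_total and ",
                 "global_count <= global_total")
    }
    m <- matrix(c(lc[i], lt[i] - lc[i], gc[i], gt[i] - gc[i]),
                nrow = 2, byrow = TRUE)
    fisher.test(m, alternative = "greater")$p.value
  }, numeric(1))
}

add_enrichment <- function(tr) {
  tr$pval <- triple_enrichment(tr$local_count, tr$local_total,
                               tr$global_count, tr$global_total)
  tr
}

#' Overlap exposure objects with outcome subjects
#'
#' Computes the overlap set O = {objects of exposure triples} \eqn{\cap}
#' {subjects of outcome triples} under normalized matching, and builds
#' the triangulation network restricted to triples incident to O:
#' exposure-side edges subject -> object (object in O) and outcome-side
#' edges subject -> object (subject in O). Enrichment p-values are
#' computed per edge when counts are available.
#'
#' @param exposure_triples,outcome_triples triple data.frames (see
#'   [read_triples()]).
#' @return object of class `triangulation_network`: list with `overlap`
#'   (sorted normalized term vector), `nodes` (term, role in
#'   exposure_subject/overlap/outcome_object), `edges` (source,
#'   predicate, target, side, pval).
#' @export
overlap_triples <- function(exposure_triples, outcome_triples) {
  et <- add_enrichment(as.data.frame(exposure_triples))
  ot <- add_enrichment(as.data.frame(outcome_triples))
  et$.obj <- normalize_term(et$object)
  et$.subj <- normalize_term(et$subject)
  ot$.subj <- normalize_term(ot$subject)
  ot$.obj <- normalize_term(ot$object)
  overlap <- sort(intersect(et$.obj, ot$.subj))

  ee <- et[et$.obj %in% overlap, , drop = FALSE]
  oe <- ot[ot$.subj %in% overlap, , drop = FALSE]
  edges <- rbind(
    data.frame(source = ee$.subj, predicate = ee$predicate,
               target = ee$.obj, side = rep_len("exposure", nrow(ee)),
               pval = ee$pval, stringsAsFactors = FALSE),
    data.frame(source = oe$.subj, predicate = oe$predicate,
               target = oe$.obj, side = rep_len("outcome", nrow(oe)),
               pval = oe$pval, stringsAsFactors = FALSE)
  )
  node_df <- function(term, role) data.frame(
    term = term, role = rep_len(role, length(term)),
    stringsAsFactors = FALSE)
  nodes <- rbind(
    node_df(setdiff(unique(ee$.subj), overlap), "exposure_subject"),
    node_df(overlap, "overlap"),
    node_df(setdiff(unique(oe$.obj), overlap), "outcome_object")
  )
  structure(list(overlap = overlap, nodes = nodes, edges = edges),
            class = "triangulation_network")
}

#' @export
print.triangulation_network <- function(x, ...) {
  cat("<triangulation_network> ", length(x$overlap), " overlap term(s), ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Rank overlap terms by best-side enrichment
#'
#' Each overlap term is scored by the smaller of its best (minimum)
#' exposure-side and best outcome-side enrichment p-value; terms are
#' ordered by that score ascending, ties broken by term. Missing
#' p-values rank last.
#'
#' @param net a `triangulation_network`.
#' @return data.frame with `term`, `best_exposure_pval`,
#'   `best_outcome_pval`, `score`, `best_exposure_edge`,
#'   `best_outcome_edge` (predicate + partner term), ordered by rank.
#' @export
rank_overlaps <- function(net) {
  stopifnot(inherits(net, "triangulation_network"))
  if (length(net$overlap) == 0) {
    return(data.frame(term = character(), best_exposure_pval = numeric(),
                      best_outcome_pval = numeric(), score = numeric(),
                      best_exposure_edge = character(),
                      best_outcome_edge = character()))
  }
  best_side <- function(term, side) {
    e <- net$edges[net$edges$side == side &
                     (if (side == "exposure") net$edges$target else
                        net$edges$source) == term, , drop = FALSE]
    if (nrow(e) == 0) return(list(p = NA_real_, lab = NA_character_))
    o <- order(e$pval, e$predicate)
    b <- e[o[1], ]
    partner <- if (side == "exposure") b$source else b$target
    list(p = b$pval, lab = paste0(partner, " -", b$predicate, "-> "))
  }
  rows <- lapply(net$overlap, function(tm) {
    be <- best_side(tm, "exposure")
    bo <- best_side(tm, "outcome")
    data.frame(term = tm, best_exposure_pval = be$p, best_outcome_pval = bo$p,
               score = suppressWarnings(min(c(be$p, bo$p), na.rm = TRUE)),
               best_exposure_edge = be$lab, best_outcome_edge = bo$lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$score[!is.finite(out$score)] <- NA_real_
  out <- out[order(is.na(out$score), out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a triangulation network to node/edge TSVs and a JSON graph
#'
#' @param net a `triangulation_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"network"`).
#' @return invisible character vector of written paths.
#' @export
write_network <- function(net, dir, prefix = "network") {
  stopifnot(inherits(net, "triangulation_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    json = file.path(dir, paste0(prefix, ".json"))
  )
  write_results(net$nodes, paths["nodes"])
  write_results(net$edges, paths["edges"])
  jsonlite::write_json(
    list(overlap = net$overlap, nodes = net$nodes, edges = net$edges),
    paths["json"], auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE
  )
  invisible(paths)
}
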