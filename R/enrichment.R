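# GO / KEGG term-enrichment engine: ontology parsing, annotation
# propagation, 2x2 contingency construction, and a one-sided Fisher exact
# test computed in log space.

#' Parse an OBO ontology file
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 flat file, keeping term id,
#' name, namespace, obsolete flag and `is_a` parent edges. The edge set is
#' checked to be acyclic. Edges pointing at terms never declared in the
#' file are an error.
#'
#' @param path Path to an `.obo` file (e.g. `go-basic.obo`).
#' @return Object of class `ontology_dag`: list with `terms` (data frame
#'   `id`, `name`, `namespace`, `obsolete`) and `parents` (named list,
#'   term id -> character vector of direct `is_a` parents).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush(cur)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(parents = character(0), obsolete = FALSE)
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+\\s*:", ln)) {
      stop("malformed OBO line ", i, ": ", ln)
    }
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+\\s*:", "", ln))
    val <- trimws(sub("\\s*!.*$", "", val))  # strip trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  flush(cur)
  if (length(terms) == 0L) stop("no [Term] stanzas in ", path)
  ids <- names(terms)
  parents <- lapply(terms, `[[`, "parents")
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing) > 0L) {
    stop("is_a edge(s) to undeclared term(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  # cycle check: Kahn peeling on the is_a graph
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (p in unlist(parents, use.names = FALSE)) indeg[p] <- indeg[p] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in parents[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(ids)) stop("cycle detected in is_a graph")
  structure(
    list(terms = data.frame(
           id = ids,
           name = vapply(terms, function(t) t$name %||% NA_character_,
                         character(1), USE.NAMES = FALSE),
           namespace = vapply(terms,
                              function(t) t$namespace %||% NA_character_,
                              character(1), USE.NAMES = FALSE),
           obsolete = vapply(terms, `[[`, logical(1), "obsolete",
                             USE.NAMES = FALSE),
           stringsAsFactors = FALSE),
         parents = parents),
    class = "ontology_dag")
}

#' All ancestors of a term through is_a edges
#'
#' @param dag An `ontology_dag` from [parse_obo()].
#' @param id Term identifier.
#' @return Character vector of ancestor term ids (excluding `id` itself).
#' @export
term_ancestors <- function(dag, id) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!id %in% names(dag$parents)) stop("unknown term: ", id)
  out <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  unique(out)
}

#' Parse a KEGG BRITE htext hierarchy (ko00001 style)
#'
#' BRITE htext files carry a four-level A/B/C/D indentation hierarchy where
#' C lines are pathways and D lines are KO entries. Each D-level KO is
#' mapped to its enclosing C-level pathway; a KO listed under several
#' pathways yields several mappings.
#'
#' @param path Path to the htext (`.keg`) file.
#' @return Object of class `pathway_hierarchy`: list with `ko2pathway`
#'   (data frame `ko`, `pathway_id`) and `pathways` (data frame
#'   `pathway_id`, `name`). KOs found before any C line are recorded in
#'   attribute `orphans` and a warning is raised.
#' @export
parse_kegg_htext <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cur_pathway <- NA_character_
  pw_id <- character(0); pw_name <- character(0)
  ko <- character(0); ko_pw <- character(0)
  orphans <- character(0)
  for (ln in lines) {
    if (!nzchar(ln)) next
    lvl <- substr(ln, 1L, 1L)
    body <- trimws(substr(ln, 2L, nchar(ln)))
    if (lvl == "C") {
      m <- regexec("^(\\d{5})\\s+(.*)$", body)[[1]]
      if (m[1L] != -1L) {
        g <- regmatches(body, regexec("^(\\d{5})\\s+(.*)$", body))[[1]]
        cur_pathway <- paste0("ko", g[2L])
        nm <- sub("\\s*\\[PATH:[^]]*\\]\\s*$", "", g[3L])
        pw_id <- c(pw_id, cur_pathway); pw_name <- c(pw_name, nm)
      } else {
        cur_pathway <- NA_character_
      }
    } else if (lvl == "D") {
      g <- regmatches(body, regexec("^(K\\d{5})\\b", body))[[1]]
      if (length(g) >= 2L) {
        if (is.na(cur_pathway)) {
          orphans <- c(orphans, g[2L])
        } else {
          ko <- c(ko, g[2L]); ko_pw <- c(ko_pw, cur_pathway)
        }
      }
    } else if (lvl %in% c("A", "B")) {
      cur_pathway <- NA_character_
    }
  }
  if (length(orphans) > 0L) {
    warning(length(orphans), " KO entr(ies) with no enclosing C-level ",
            "pathway: ", paste(utils::head(orphans, 5L), collapse = ", "))
  }
  map <- unique(data.frame(ko = ko, pathway_id = ko_pw,
                           stringsAsFactors = FALSE))
  pws <- unique(data.frame(pathway_id = pw_id, name = pw_name,
                           stringsAsFactors = FALSE))
  structure(list(ko2pathway = map, pathways = pws, orphans = orphans),
            class = "pathway_hierarchy")
}

#' Propagate gene annotations up the ontology
#'
#' Annotates every gene to all is_a ancestors of its directly assigned
#' terms (the standard "true-path" convention for GO). Obsolete terms and
#' terms absent from the DAG are dropped with a warning.
#'
#' @param annotations Data frame with columns `gene`, `term`.
#' @param dag An `ontology_dag`.
#' @param propagate Set `FALSE` to return the (cleaned) direct annotations
#'   unchanged.
#' @return Data frame `gene`, `term` with one row per (gene, term) pair.
#' @export
propagate_annotations <- function(annotations, dag, propagate = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"),
            all(c("gene", "term") %in% names(annotations)))
  known <- annotations$term %in% names(dag$parents)
  if (any(!known)) {
    warning("dropping ", sum(!known), " annotation(s) to unknown term(s)")
    annotations <- annotations[known, , drop = FALSE]
  }
  obs <- dag$terms$id[dag$terms$obsolete]
  if (length(obs) > 0L) {
    annotations <- annotations[!annotations$term %in% obs, , drop = FALSE]
  }
  if (!propagate || nrow(annotations) == 0L) {
    return(unique(annotations[, c("gene", "term")]))
  }
  anc <- lapply(stats::setNames(nm = unique(annotations$term)),
                function(t) c(t, setdiff(term_ancestors(dag, t), obs)))
  reps <- lengths(anc[annotations$term])
  out <- data.frame(
    gene = rep(annotations$gene, reps),
    term = unlist(anc[annotations$term], use.names = FALSE),
    stringsAsFactors = FALSE)
  unique(out)
}

#' Build the 2x2 contingency table for one term
#'
#' Cells follow the usual enrichment layout: `a` study genes annotated to
#' the term, `b` study genes not annotated, `c` background genes with the
#' term outside the study, `d` the remaining background.
#'
#' @param term Term identifier.
#' @param study_genes Character vector, must be a subset of the background.
#' @param background_genes Character vector defining the population.
#' @param annotations Data frame `gene`, `term` (already propagated if
#'   desired).
#' @return Object of class `contingency_table`: named integer vector
#'   `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(term, study_genes, background_genes,
                              annotations) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  extra <- setdiff(study_genes, background_genes)
  if (length(extra) > 0L) {
    stop("study gene(s) outside background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  with_term <- unique(annotations$gene[annotations$term == term])
  with_term <- intersect(with_term, background_genes)
  a <- length(intersect(study_genes, with_term))
  b <- length(study_genes) - a
  cc <- length(with_term) - a
  d <- length(background_genes) - a - b - cc
  structure(c(a = a, b = b, c = cc, d = d), class = "contingency_table")
}

#' One-sided (enrichment) Fisher exact test
#'
#' Computes the exact upper-tail hypergeometric probability
#' P(X >= a) for a 2x2 table with fixed margins, i.e. the one-sided
#' Fisher exact p-value for over-representation. The tail is summed in log
#' space from `lchoose` terms, so the computation is stable for populations
#' up to at least 1e6. All four arguments are vectorized.
#'
#' @param a,b,c,d Non-negative cell counts (see [build_contingency()]);
#'   alternatively pass a single `contingency_table` as `a`.
#' @return p-value(s) in \[0, 1\].
#' @export
fisher_exact_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_table")) {
    b <- a[["b"]]; c <- a[["c"]]; d <- a[["d"]]; a <- a[["a"]]
  }
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d),
            all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  K <- a + c          # background genes with term
  n <- a + b          # study size
  N <- a + b + c + d  # background size
  upper <- pmin(K, n)
  ntab <- length(a)
  width <- upper - a + 1L
  idx <- rep.int(seq_len(ntab), width)
  x <- sequence(width) - 1L + a[idx]
  logp <- lchoose(K[idx], x) + lchoose(N[idx] - K[idx], n[idx] - x) -
    lchoose(N[idx], n[idx])
  p <- as.numeric(rowsum(exp(logp), idx, reorder = TRUE))
  p <- pmin(p, 1)
  p[a == 0L] <- 1       # lower tail is complete by definition
  p
}

# Two-sided Fisher p: sum of all outcome probabilities not exceeding the
# observed one (same convention as stats::fisher.test).
fisher_exact_two_sided <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  xs <- max(0L, n - (N - K)):min(K, n)
  logp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  pobs <- logp[xs == a]
  min(1, sum(exp(logp[logp <= pobs + 1e-7])))
}

#' Run term enrichment over a study set
#'
#' For every term annotated to at least one study gene, builds the 2x2
#' contingency table against the background, computes the one-sided Fisher
#' exact p-value and the fold enrichment
#' (study proportion / background proportion), and flags significance.
#'
#' @param study_genes Character vector of study gene identifiers.
#' @param annotations Data frame `gene`, `term`.
#' @param background_genes Population; defaults to all genes carrying at
#'   least one annotation.
#' @param dag Optional `ontology_dag`; when given, annotations are
#'   propagated through is_a edges (see `propagate`).
#' @param alpha Significance level on the (possibly adjusted) p-value.
#'   Default 0.01.
#' @param correction `"none"` (default) or `"BH"`
#'   (Benjamini-Hochberg via [stats::p.adjust()]).
#' @param propagate Propagate annotations through `dag` (default TRUE,
#'   ignored when `dag` is NULL).
#' @param alternative `"greater"` (default, enrichment only) or
#'   `"two.sided"`.
#' @return Data frame with `term`, `a`, `b`, `c`, `d`, `p_value`,
#'   `fold_enrichment`, `p_adjusted`, `significant`, sorted by descending
#'   fold enrichment then ascending p.
#' @export
run_enrichment <- function(study_genes, annotations,
                           background_genes = NULL, dag = NULL,
                           alpha = 0.01, correction = c("none", "BH"),
                           propagate = TRUE,
                           alternative = c("greater", "two.sided")) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  study_genes <- unique(study_genes)
  if (length(study_genes) == 0L) stop("empty study set")
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  if (!is.null(dag)) {
    annotations <- propagate_annotations(annotations, dag,
                                         propagate = propagate)
  } else {
    annotations <- unique(annotations[, c("gene", "term")])
  }
  if (is.null(background_genes)) {
    background_genes <- unique(annotations$gene)
  }
  background_genes <- unique(background_genes)
  extra <- setdiff(study_genes, background_genes)
  if (length(extra) > 0L) {
    stop("study gene(s) outside background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  annotations <- annotations[annotations$gene %in% background_genes, ,
                             drop = FALSE]
  N <- length(background_genes)
  nstudy <- length(study_genes)
  term_total <- table(annotations$term)
  in_study <- annotations$gene %in% study_genes
  term_a <- table(annotations$term[in_study])
  terms <- names(term_a)           # every term with a >= 1
  if (length(terms) == 0L) {
    return(data.frame(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p_value = numeric(),
                      fold_enrichment = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  a <- as.integer(term_a[terms])
  K <- as.integer(term_total[terms])
  b <- nstudy - a
  cc <- K - a
  d <- N - nstudy - cc
  p <- if (alternative == "greater") {
    fisher_exact_greater(a, b, cc, d)
  } else {
    mapply(fisher_exact_two_sided, a, b, cc, d)
  }
  fold <- (a / nstudy) / (K / N)
  padj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  out <- data.frame(term = terms, a = a, b = b, c = cc, d = d,
                    p_value = p, fold_enrichment = fold,
                    p_adjusted = padj, significant = padj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_enrichment, out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
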