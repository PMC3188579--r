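#' Read a GO-style term DAG
#'
#' Accepts either an OBO-flavored flat file (stanzas headed `[Term]` with
#' `id:`, `name:`, and `is_a:`/`part_of:` parent lines) or a 3-column TSV
#' (id, name, comma-separated parents). Only is_a/part_of parentage is kept.
#'
#' @param x path to the file, or a character vector of its lines.
#' @return object of class `go_dag`: list with `terms` (data.frame id, name),
#'   `parents` (named list id -> character vector of parent ids), and the
#'   `igraph` child-to-parent graph.
#' @export
read_go_dag <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  ids <- names <- character(0)
  parents <- list()
  if (any(startsWith(lines, "[Term]"))) {
    cur <- NULL
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "[Term]") { cur <- NULL; next }
      if (startsWith(ln, "id:")) {
        cur <- trimws(sub("^id:", "", ln))
        ids <- c(ids, cur); names <- c(names, ""); parents[[cur]] <- character(0)
      } else if (!is.null(cur) && startsWith(ln, "name:")) {
        names[length(names)] <- trimws(sub("^name:", "", ln))
      } else if (!is.null(cur) && startsWith(ln, "is_a:")) {
        p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        parents[[cur]] <- c(parents[[cur]], p)
      } else if (!is.null(cur) && startsWith(ln, "relationship: part_of")) {
        p <- trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln)))
        parents[[cur]] <- c(parents[[cur]], p)
      }
    }
  } else {
    for (ln in lines) {
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      ids <- c(ids, f[1])
      names <- c(names, if (length(f) >= 2L) f[2] else "")
      parents[[f[1]]] <- if (length(f) >= 3L && nzchar(f[3])) {
        strsplit(f[3], ",", fixed = TRUE)[[1]]
      } else character(0)
    }
  }
  abort_if(anyDuplicated(ids) > 0, "duplicate term ids")
  unknown <- setdiff(unlist(parents), ids)
  abort_if(length(unknown) > 0, "parent terms not defined: ",
           paste(unknown, collapse = ", "))
  edges <- do.call(rbind, lapply(ids, function(i) {
    if (length(parents[[i]])) cbind(i, parents[[i]]) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE,
    vertices = data.frame(name = ids))
  abort_if(!igraph::is_dag(g) && length(ids) > 1L && igraph::ecount(g) > 0,
           "parent graph contains a cycle")
  structure(list(terms = data.frame(id = ids, name = names,
                                    stringsAsFactors = FALSE),
                 parents = parents, graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", nrow(x$terms), "terms,", igraph::ecount(x$graph),
      "is_a/part_of edges\n")
  invisible(x)
}

#' Read gene-to-term annotations
#'
#' Two-column tab-delimited input: gene id, term id (one pair per line).
#' Genes annotated to terms absent from the DAG are dropped with a warning.
#'
#' @param x path or character vector of lines.
#' @param dag a `go_dag`.
#' @return named list gene -> character vector of directly annotated terms.
#' @export
read_annotations <- function(x, dag) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(f, `[`, "", 1L)
  term <- vapply(f, `[`, "", 2L)
  known <- term %in% dag$terms$id
  if (any(!known)) {
    warning(sum(!known), " annotation(s) to terms absent from the DAG dropped")
  }
  lapply(split(term[known], gene[known]), unique)
}

#' Propagate annotations to ancestor terms
#'
#' The annotation closure: a gene is annotated to a term if any of its direct
#' terms has a directed is_a/part_of path to it (every term is its own
#' ancestor).
#'
#' @param annotations named list gene -> direct term ids.
#' @param dag a `go_dag`.
#' @return named list gene -> closed term set.
#' @export
annotation_closure <- function(annotations, dag) {
  anc <- ancestors_table(dag)
  lapply(annotations, function(terms) {
    sort(unique(unlist(anc[terms], use.names = FALSE)))
  })
}

# term -> all ancestors including itself (memoized per dag call)
ancestors_table <- function(dag) {
  ids <- dag$terms$id
  out <- lapply(ids, function(t) {
    igraph::subcomponent(dag$graph, t, mode = "out")$name
  })
  stats::setNames(out, ids)
}

# shared scaffolding: per-term study/population hit counts on the closure
term_counts <- function(study, population, closure) {
  study <- intersect(study, names(closure))
  population <- intersect(population, names(closure))
  pop_terms <- table(unlist(closure[population], use.names = FALSE))
  st_terms <- table(unlist(closure[study], use.names = FALSE))
  list(study = study, population = population,
       M = pop_terms, m = st_terms)
}

enrichment_frame <- function(term, study_hits, study_size, pop_hits, pop_size,
                             p, method) {
  data.frame(term_id = term, study_hits = as.integer(study_hits),
             study_size = as.integer(study_size),
             population_hits = as.integer(pop_hits),
             population_size = as.integer(pop_size),
             p_value = p, method = method, stringsAsFactors = FALSE)
}

drop_unannotated <- function(study, population, closure) {
  n0 <- length(study) + length(population)
  study <- intersect(study, names(closure))
  population <- union(intersect(population, names(closure)), study)
  dropped <- n0 - (length(study) + length(population))
  if (dropped > 0) {
    message(dropped, " gene(s) without annotations dropped from the analysis")
  }
  list(study = study, population = population)
}

#' Term-for-term GO enrichment
#'
#' Upper-tail hypergeometric test per term: with N population genes of which
#' M are annotated (via the closure) to the term, and a study set of n genes
#' containing m annotated ones, p = P(X >= m), X ~ Hypergeom(N, M, n). Terms
#' annotating no population gene are skipped.
#'
#' @param study character vector of significant gene ids (subset of
#'   `population`).
#' @param population character vector of all tested gene ids.
#' @param dag a `go_dag`.
#' @param annotations named list gene -> direct terms (see
#'   [read_annotations()]).
#' @param adjust apply Benjamini-Hochberg adjustment in an extra `p_adjusted`
#'   column (off by default).
#' @return data.frame of enrichment rows, one per testable term.
#' @export
term_for_term <- function(study, population, dag, annotations,
                          adjust = FALSE) {
  abort_if(!all(study %in% population), "study must be a subset of population")
  closure <- annotation_closure(annotations, dag)
  sp <- drop_unannotated(study, population, closure)
  tc <- term_counts(sp$study, sp$population, closure)
  N <- length(tc$population); n <- length(tc$study)
  terms <- names(tc$M)
  m <- as.integer(tc$m[terms]); m[is.na(m)] <- 0L
  M <- as.integer(tc$M[terms])
  p <- phyper(m - 1L, M, N - M, n, lower.tail = FALSE)
  out <- enrichment_frame(terms, m, n, M, N, p, "term_for_term")
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$term_id), ]
}

#' Parent-child GO enrichment (intersection variant)
#'
#' Conditions each term's hypergeometric test on its parents: the population
#' is restricted to genes annotated (closure) to *all* parents of the term,
#' and the study side to study genes within that restriction. Root terms
#' (no parents) get p = 1 by convention, as do terms whose annotation set
#' equals the parent restriction (no refinement possible).
#'
#' @inheritParams term_for_term
#' @return data.frame of enrichment rows.
#' @export
parent_child <- function(study, population, dag, annotations,
                         adjust = FALSE) {
  abort_if(!all(study %in% population), "study must be a subset of population")
  closure <- annotation_closure(annotations, dag)
  sp <- drop_unannotated(study, population, closure)
  tc <- term_counts(sp$study, sp$population, closure)
  terms <- names(tc$M)
  gene_terms_pop <- closure[sp$population]
  gene_terms_study <- closure[sp$study]
  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    t <- terms[i]
    pars <- dag$parents[[t]]
    if (is.null(pars) || !length(pars)) {
      rows[[i]] <- enrichment_frame(t, as.integer(tc$m[t] %|na|% 0L),
                                    length(sp$study), as.integer(tc$M[t]),
                                    length(sp$population), 1, "parent_child")
      next
    }
    in_pop <- vapply(gene_terms_pop, function(ts) all(pars %in% ts),
                     logical(1))
    in_study <- vapply(gene_terms_study, function(ts) all(pars %in% ts),
                       logical(1))
    Np <- sum(in_pop); np <- sum(in_study)
    Mp <- sum(vapply(gene_terms_pop[in_pop], function(ts) t %in% ts,
                     logical(1)))
    mp <- sum(vapply(gene_terms_study[in_study], function(ts) t %in% ts,
                     logical(1)))
    p <- if (Mp == 0L || Np == 0L) 1 else
      phyper(mp - 1L, Mp, Np - Mp, np, lower.tail = FALSE)
    rows[[i]] <- enrichment_frame(t, mp, np, Mp, Np, p, "parent_child")
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$term_id), ]
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Permutation GO enrichment
#'
#' Empirical null built by redrawing the study set: each permutation samples
#' |study| genes uniformly without replacement from the population, and the
#' per-term p-value is (1 + #{permutations with m* >= m}) / (n_perm + 1).
#' Seeded and reproducible.
#'
#' @inheritParams term_for_term
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return data.frame of enrichment rows.
#' @export
perm_enrichment <- function(study, population, dag, annotations,
                            n_perm = 1000L, seed = 1L, adjust = FALSE) {
  abort_if(n_perm < 100L, "n_perm must be at least 100")
  abort_if(!all(study %in% population), "study must be a subset of population")
  closure <- annotation_closure(annotations, dag)
  sp <- drop_unannotated(study, population, closure)
  tc <- term_counts(sp$study, sp$population, closure)
  terms <- names(tc$M)
  m_obs <- as.integer(tc$m[terms]); m_obs[is.na(m_obs)] <- 0L
  # gene x term incidence for fast permutation tallies
  inc <- matrix(FALSE, nrow = length(sp$population), ncol = length(terms),
                dimnames = list(sp$population, terms))
  for (g in sp$population) inc[g, intersect(closure[[g]], terms)] <- TRUE
  n <- length(sp$study)
  exceed <- integer(length(terms))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      draw <- sample(sp$population, n)
      m_star <- colSums(inc[draw, , drop = FALSE])
      exceed <- exceed + (m_star >= m_obs)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  out <- enrichment_frame(terms, m_obs, n, as.integer(tc$M[terms]),
                          length(sp$population), p, "permutation")
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$term_id), ]
}
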