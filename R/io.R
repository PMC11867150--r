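# On-disk formats: FASTA alignments with abundance TSVs, histories as
# newick + FASTA pairs (node names resolve to sequences), history sDAGs
# as a documented JSON schema, and the PHYLIP dnapars "outfile" dialect.

# ---------------------------------------------------------------------------
# alignments + abundances

#' Read a FASTA alignment with per-sequence abundance counts
#'
#' Sequences are validated (equal lengths, IUPAC alphabet, unique ids),
#' upcased if needed, and deduplicated into genotypes with summed counts.
#' The TSV has two columns (sequence id, count) with no header; ids absent
#' from the TSV, or the whole file when `tsv_path` is `NULL`, default to
#' count 1.
#'
#' @param fasta_path Path to a FASTA alignment.
#' @param tsv_path Optional path to the abundance TSV.
#' @return List with `sequences` (named character vector, one entry per
#'   genotype, named by the first id carrying it), `abundances` (integer
#'   vector named by genotype sequence) and `ids` (the full id to
#'   sequence map before deduplication).
#' @export
read_alignment_with_abundances <- function(fasta_path, tsv_path = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  if (anyDuplicated(names(dna))) {
    stop("duplicate sequence ids in FASTA", call. = FALSE)
  }
  seqs <- vapply(as.character(dna), function(x) {
    paste(toupper(x), collapse = "")
  }, character(1L))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  lapply(seqs, .check_label)
  counts <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  if (!is.null(tsv_path)) {
    tb <- utils::read.delim(tsv_path, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(tb) < 2L) stop("abundance TSV needs id and count columns",
                            call. = FALSE)
    if (anyDuplicated(tb[[1L]])) {
      stop("duplicate ids in abundance TSV", call. = FALSE)
    }
    unknown <- setdiff(tb[[1L]], names(seqs))
    if (length(unknown) > 0L) {
      stop("abundance TSV ids missing from FASTA: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    counts[tb[[1L]]] <- as.integer(tb[[2L]])
  }
  first <- !duplicated(seqs)
  genotype <- seqs[first]
  abund <- vapply(genotype, function(g) {
    sum(counts[names(seqs)[seqs == g]])
  }, integer(1L))
  names(abund) <- unname(genotype)
  list(sequences = genotype, abundances = abund, ids = seqs)
}

#' Write sequences to FASTA / abundances to TSV
#' @param sequences Named character vector (id to sequence).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(c(paste0(">", id), sequences[[id]]), con)
  }
  invisible(path)
}

#' @param abundances Integer vector named by sequence id.
#' @rdname write_fasta
#' @export
write_abundances <- function(abundances, path) {
  utils::write.table(
    data.frame(id = names(abundances), count = as.integer(abundances)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# histories as newick + FASTA

#' Read a history from a newick topology and a node-sequence FASTA
#'
#' The newick file carries the rooted topology with named internal nodes;
#' the FASTA maps every node name (leaf and internal) to its sequence.
#' Branch lengths, if present, are ignored: ranking criteria are
#' sequence-based.
#'
#' @param newick_path Path to a newick file.
#' @param fasta_path Path to the node-sequence FASTA.
#' @return A `history`; attribute `"node_names"` maps sequences back to node
#'   names for round-tripping.
#' @export
read_history <- function(newick_path, fasta_path) {
  tr <- ape::read.tree(newick_path)
  dna <- ape::read.FASTA(fasta_path)
  seqs <- vapply(as.character(dna), function(x) {
    paste(toupper(x), collapse = "")
  }, character(1L))
  lookup <- function(name) {
    if (!name %in% names(seqs)) {
      stop("node name without a sequence in FASTA: ", name, call. = FALSE)
    }
    seqs[[name]]
  }
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  build <- function(idx) {
    if (idx <= n_tip) return(history_node(lookup(tr$tip.label[[idx]])))
    name <- tr$node.label[[idx - n_tip]]
    if (is.null(name) || is.na(name) || !nzchar(name)) {
      stop("internal nodes must be named in the newick file", call. = FALSE)
    }
    history_node(lookup(name),
                 lapply(kids[[as.character(idx)]], build))
  }
  h <- as_history(build(n_tip + 1L))
  validate_history(h)
  attr(h, "node_names") <- stats::setNames(names(seqs), seqs)
  h
}

#' Write a history as newick + FASTA
#'
#' @param h A `history`.
#' @param newick_path,fasta_path Output paths.
#' @param names Optional named character vector mapping sequences to node
#'   names; unnamed nodes get `seqN` (leaves) / `ancestralN` (internal)
#'   identifiers.
#' @return Invisibly, the sequence-to-name map used.
#' @export
write_history <- function(h, newick_path, fasta_path, names = NULL) {
  counter <- c(leaf = 0L, internal = 0L)
  seq_names <- new.env(hash = TRUE, parent = emptyenv())
  fasta <- list()
  name_of <- function(label, is_leaf) {
    nm <- seq_names[[label]]
    if (!is.null(nm)) return(nm)
    if (!is.null(names) && label %in% base::names(names)) {
      nm <- names[[label]]
    } else if (is_leaf) {
      counter["leaf"] <<- counter[["leaf"]] + 1L
      nm <- paste0("seq", counter[["leaf"]])
    } else {
      counter["internal"] <<- counter[["internal"]] + 1L
      nm <- paste0("ancestral", counter[["internal"]])
    }
    seq_names[[label]] <- nm
    fasta[[nm]] <<- label
    nm
  }
  nwk <- function(node) {
    if (length(node$children) == 0L) {
      return(name_of(node$label, TRUE))
    }
    paste0("(", paste(vapply(node$children, nwk, character(1L)),
                      collapse = ","), ")",
           name_of(node$label, FALSE))
  }
  writeLines(paste0(nwk(h), ";"), newick_path)
  write_fasta(unlist(fasta), fasta_path)
  invisible(stats::setNames(base::names(unlist(fasta)),
                            unname(unlist(fasta))))
}

# ---------------------------------------------------------------------------
# DAG JSON serialization

#' Serialize / deserialize a history sDAG as JSON
#'
#' Schema (version 1): `leaves` is the sorted leaf label array; `nodes` is
#' a table of `{id, label, clades}` where clades are arrays of sorted
#' 1-based indices into `leaves` (leaves have no clades); `edges` is an
#' array of `[parent_id, clade_index, child_id]` triples (1-based) and
#' `ua` lists the UA node's child ids.  Paths ending in `.gz` are
#' gzip-compressed.
#'
#' @param dag A `history_sdag`.
#' @param path Output path (`.json` or `.json.gz`).
#' @return `read_dag_json` returns a `history_sdag`.
#' @export
write_dag_json <- function(dag, path) {
  keys <- names(dag$nodes)
  id_of <- stats::setNames(seq_along(keys), keys)
  leaf_id <- stats::setNames(seq_along(dag$leaves), dag$leaves)
  nodes <- lapply(keys, function(k) {
    node <- dag$nodes[[k]]
    list(id = id_of[[k]], label = node$label,
         clades = lapply(node$clades, function(cl) {
           as.integer(sort(leaf_id[cl]))
         }))
  })
  edges <- list()
  for (k in keys) {
    e <- dag$edges[[k]]
    for (i in seq_along(e)) {
      for (c in e[[i]]) {
        edges[[length(edges) + 1L]] <-
          c(id_of[[k]], i, id_of[[c]])
      }
    }
  }
  obj <- list(version = 1L, seq_length = dag$seq_length,
              leaves = dag$leaves, nodes = nodes, edges = edges,
              ua = unname(id_of[dag$ua]))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  close(con)
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = ""),
                            simplifyVector = FALSE)
  close(con)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported DAG JSON version", call. = FALSE)
  }
  leaves <- unlist(obj$leaves)
  recs <- lapply(obj$nodes, function(n) {
    clades <- lapply(n$clades, function(cl) {
      sort(leaves[unlist(cl)])
    })
    .make_node_record(n$label, clades)
  })
  ids <- vapply(obj$nodes, function(n) n$id, numeric(1L))
  key_of <- stats::setNames(vapply(recs, `[[`, character(1L), "key"),
                            as.character(ids))
  nodes <- stats::setNames(recs, unname(key_of[as.character(ids)]))
  edges <- lapply(nodes, function(n) {
    rep(list(character(0L)), length(n$clades))
  })
  names(edges) <- names(nodes)
  for (e in obj$edges) {
    e <- unlist(e)
    pk <- key_of[[as.character(e[[1L]])]]
    ck <- key_of[[as.character(e[[3L]])]]
    i <- e[[2L]]
    edges[[pk]][[i]] <- sort(union(edges[[pk]][[i]], ck))
  }
  ua <- sort(unname(key_of[as.character(unlist(obj$ua))]))
  dag <- .new_sdag(nodes, edges, ua, sort(leaves),
                   as.integer(obj$seq_length))
  validate_sdag(dag)
  dag
}

# ---------------------------------------------------------------------------
# dnapars outfile parser

#' Parse a PHYLIP dnapars "outfile"
#'
#' Parses the ancestral-state table dialect printed by dnapars: each tree
#' section begins with a line containing `requires a total of`, followed
#' by one or more blocks headed `From    To     Any Steps?    State at
#' upper node`.  Data rows carry an optional parent id, a node id, an
#' optional yes/no/maybe flag, and whitespace-separated sequence chunks in
#' which `.` means "same base as the parent at this position"; chunks from
#' repeated blocks are concatenated in row order.  The root row has no
#' parent id.  Internal nodes are numbered; leaves keep their alignment
#' names.
#'
#' @param path Path to a dnapars outfile.
#' @return List of `history` objects with ambiguity codes preserved;
#'   each carries a `"node_names"` attribute mapping sequences to node names.
#' @export
parse_dnapars_outfile <- function(path) {
  lines <- readLines(path)
  starts <- grep("requires a total of", lines)
  if (length(starts) == 0L) {
    stop("no trees found in dnapars outfile (no 'requires a total of' line)",
         call. = FALSE)
  }
  sections <- mapply(function(from, to) lines[from:to],
                     starts, c(starts[-1L] - 1L, length(lines)),
                     SIMPLIFY = FALSE)
  lapply(sections, .parse_dnapars_section)
}

.parse_dnapars_section <- function(lines) {
  seq_re <- "^[ACGTURYSWKMBDHVN.?-]+$"
  order_ids <- character(0L)
  parent <- list()
  chunks <- list()
  in_block <- FALSE
  for (ln in lines) {
    if (grepl("From\\s+To\\s+Any Steps", ln)) {
      in_block <- TRUE
      next
    }
    if (!in_block) next
    if (grepl("means same as in the node below", ln)) next
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    is_seq <- grepl(seq_re, toks)
    # trailing run of sequence tokens
    k <- length(toks)
    while (k >= 1L && is_seq[[k]]) k <- k - 1L
    head_toks <- toks[seq_len(k)]
    seq_toks <- if (k < length(toks)) toks[(k + 1L):length(toks)] else
      character(0L)
    head_toks <- setdiff(head_toks, c("yes", "no", "maybe"))
    # lines without sequence chunks (e.g. ASCII tree art) are not data rows
    if (length(seq_toks) == 0L) next
    if (length(head_toks) == 1L) {
      id <- head_toks[[1L]]
      par <- NA_character_
    } else if (length(head_toks) == 2L) {
      par <- head_toks[[1L]]
      id <- head_toks[[2L]]
    } else {
      stop("malformed dnapars row: ", ln, call. = FALSE)
    }
    if (!id %in% order_ids) {
      order_ids <- c(order_ids, id)
      parent[[id]] <- par
      chunks[[id]] <- character(0L)
    }
    chunks[[id]] <- c(chunks[[id]], seq_toks)
  }
  if (length(order_ids) == 0L) {
    stop("empty dnapars tree section", call. = FALSE)
  }
  seqs <- vapply(order_ids, function(id) {
    toupper(paste(chunks[[id]], collapse = ""))
  }, character(1L))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("inconsistent sequence lengths in dnapars section", call. = FALSE)
  }
  # resolve '.' (same as parent) root-down
  roots <- order_ids[vapply(order_ids, function(id) is.na(parent[[id]]),
                            logical(1L))]
  if (length(roots) != 1L) {
    stop("dnapars section must have exactly one root row", call. = FALSE)
  }
  resolved <- new.env(hash = TRUE, parent = emptyenv())
  resolve <- function(id) {
    if (!is.null(resolved[[id]])) return(resolved[[id]])
    s <- strsplit(seqs[[id]], "", fixed = TRUE)[[1L]]
    if (!is.na(parent[[id]])) {
      p <- strsplit(resolve(parent[[id]]), "", fixed = TRUE)[[1L]]
      dots <- s == "."
      s[dots] <- p[dots]
    } else if (any(s == ".")) {
      stop("root row may not contain '.' characters", call. = FALSE)
    }
    s[s == "?"] <- "N"
    out <- paste(s, collapse = "")
    resolved[[id]] <- out
    out
  }
  for (id in order_ids) resolve(id)
  kids <- split(order_ids,
                vapply(order_ids, function(id) {
                  p <- parent[[id]]
                  if (is.na(p)) "" else p
                }, character(1L)))
  build <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) return(history_node(resolved[[id]]))
    history_node(resolved[[id]], lapply(ch, build))
  }
  h <- as_history(build(roots[[1L]]))
  attr(h, "node_names") <- stats::setNames(
    order_ids, vapply(order_ids, function(id) resolved[[id]],
                      character(1L)))
  h
}
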