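# GlycanTree: rooted labeled tree of monosaccharide residues with
# linkage-annotated edges, parsed from and written to a condensed text
# form, e.g. "Neu5Ac(a2-6)GalNAc(a1-" for the sialyl-Tn antigen.
#
# Grammar (reading left = non-reducing end, right = reducing end):
#   chain    := unit+ ; last unit is the (sub)root
#   unit     := branch* mod* NAME linkage
#   branch   := "[" chain "]"            (chain's root attaches to the
#                                         residue that follows the bracket)
#   mod      := POSITION LETTERS "-"     (e.g. "9Ac-" for 9-O-acetylation)
#   linkage  := "(" anomer DIGIT "-" DIGIT ")"   internal edge
#             | "(" anomer DIGIT "-"             open reducing end (root)
#   anomer   := "a" | "b"

#' Monosaccharide names known to the parser and builder
#' @return character vector of residue names.
#' @export
residue_names <- function() {
  c("Neu5Ac", "Neu5Gc", "GalNAc", "GlcNAc", "Gal", "Glc", "Man", "Fuc")
}

# Anomeric carbon number by residue: 2 for sialic acids, 1 otherwise.
.anomeric_pos <- function(name) ifelse(grepl("^Neu", name), 2L, 1L)

.new_glycan_tree <- function(residues, edges, root, aglycon = NA_character_) {
  residues <- residues[order(residues$id), , drop = FALSE]
  rownames(residues) <- NULL
  rownames(edges) <- NULL
  obj <- structure(list(residues = residues, edges = edges,
                        root = root, aglycon = aglycon),
                   class = "glycan_tree")
  .validate_glycan_tree(obj)
  obj
}

.validate_glycan_tree <- function(tree) {
  res <- tree$residues
  ed <- tree$edges
  if (!all(res$name %in% residue_names())) {
    bad <- setdiff(res$name, residue_names())
    stop("unknown residue name: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(ed) != nrow(res) - 1) {
    stop("glycan tree must have exactly n-1 edges", call. = FALSE)
  }
  if (nrow(ed) > 0) {
    if (any(!ed$child %in% res$id) || any(!ed$parent %in% res$id)) {
      stop("edge references unknown residue id", call. = FALSE)
    }
    if (anyDuplicated(ed$child) > 0) {
      stop("a residue cannot have two parents", call. = FALSE)
    }
    if (tree$root %in% ed$child) stop("root cannot be a child", call. = FALSE)
    occ <- paste(ed$parent, ed$parent_pos)
    if (anyDuplicated(occ) > 0) {
      stop("parent attachment position occupied twice", call. = FALSE)
    }
    # modifications may not collide with an edge at the same position
    for (k in seq_len(nrow(ed))) {
      mods <- .mod_list(res$mods[res$id == ed$parent[k]])
      mp <- as.integer(sub("[A-Za-z]+$", "", mods))
      if (ed$parent_pos[k] %in% mp) {
        stop("attachment position ", ed$parent_pos[k],
             " carries both an edge and a modification", call. = FALSE)
      }
    }
    # connectivity: everything reaches the root
    reach <- tree$root
    repeat {
      nxt <- ed$child[ed$parent %in% reach & !ed$child %in% reach]
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    if (length(reach) != nrow(res)) {
      stop("glycan tree is not connected", call. = FALSE)
    }
  }
  invisible(tree)
}

.mod_list <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) character(0) else strsplit(mods, ";")[[1]]
}

#' Parse a condensed glycan string into a GlycanTree
#'
#' @param text glycan in condensed text form, written non-reducing to
#'   reducing end, e.g. `"Neu5Ac(a2-6)GalNAc(a1-"`. Branches are enclosed
#'   in square brackets; modifications are hyphenated prefixes
#'   (`"9Ac-Neu5Ac..."`).
#' @return object of class `glycan_tree` with elements `residues`
#'   (id, name, anomer, ano_pos, mods), `edges` (child, parent, child_pos,
#'   parent_pos), `root` and `aglycon`.
#' @examples
#' stn <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")
#' write_glycan(stn)
#' @export
parse_glycan <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s+", "", text)
  if (!nzchar(s)) stop("empty glycan string", call. = FALSE)
  units <- .parse_chain(s, top = TRUE)
  env <- new.env()
  env$next_id <- 1L
  env$residues <- list()
  env$edges <- list()
  rootinfo <- .emit_chain(units, env)
  residues <- do.call(rbind, env$residues)
  edges <- if (length(env$edges) > 0) {
    do.call(rbind, env$edges)
  } else {
    data.frame(child = integer(0), parent = integer(0),
               child_pos = integer(0), parent_pos = integer(0))
  }
  .new_glycan_tree(residues, edges, root = rootinfo$id)
}

# Split one chain string into a list of unit records.
.parse_chain <- function(s, top = FALSE) {
  units <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    branches <- list()
    while (substr(s, i, i) == "[") {
      j <- .match_bracket(s, i)
      branches[[length(branches) + 1]] <- .parse_chain(substr(s, i + 1, j - 1))
      i <- j + 1L
    }
    if (substr(s, i, i) == "]") {
      stop(sprintf("glycan parse error: unmatched ']' at position %d", i),
           call. = FALSE)
    }
    rest <- substr(s, i, n)
    m <- regexec("^((?:[0-9][A-Za-z0-9]*-)*)([A-Za-z0-9]+)\\(([ab])([0-9])-([0-9]?)(\\)?)",
                 rest)[[1]]
    if (m[1] == -1) {
      tok <- sub("[\\(\\[].*$", "", rest)
      stop(sprintf("glycan parse error near position %d: cannot read residue '%s'",
                   i, tok), call. = FALSE)
    }
    g <- regmatches(rest, list(m))[[1]]
    modstr <- g[2]
    name <- g[3]
    anomer <- g[4]
    child_pos <- as.integer(g[5])
    parent_pos <- if (nzchar(g[6])) as.integer(g[6]) else NA_integer_
    closed <- nzchar(g[7])
    if (!name %in% residue_names()) {
      stop(sprintf("glycan parse error: unknown residue name '%s'", name),
           call. = FALSE)
    }
    if (!is.na(parent_pos) && !closed) {
      stop("glycan parse error: linkage missing closing ')'", call. = FALSE)
    }
    mods <- if (nzchar(modstr)) {
      strsplit(sub("-$", "", modstr), "-")[[1]]
    } else {
      character(0)
    }
    units[[length(units) + 1]] <- list(
      name = name, anomer = anomer, child_pos = child_pos,
      parent_pos = parent_pos, mods = mods, branches = branches)
    i <- i + attr(m, "match.length")[1]
    if (is.na(parent_pos)) {
      # open reducing end: must terminate the chain
      if (i <= n) {
        stop("glycan parse error: text after open reducing end", call. = FALSE)
      }
      if (!top) {
        stop("glycan parse error: branch chain lacks an attachment position",
             call. = FALSE)
      }
    }
  }
  if (length(units) == 0) {
    stop("glycan parse error: empty chain", call. = FALSE)
  }
  last <- units[[length(units)]]
  if (top && !is.na(last$parent_pos)) {
    stop("glycan parse error: reducing-end residue must end with an open linkage like '(a1-'",
         call. = FALSE)
  }
  units
}

.match_bracket <- function(s, i) {
  depth <- 0L
  for (k in i:nchar(s)) {
    ch <- substr(s, k, k)
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      depth <- depth - 1L
      if (depth == 0L) return(k)
    }
  }
  stop(sprintf("glycan parse error: unmatched '[' at position %d", i),
       call. = FALSE)
}

# Assign ids and collect residue/edge rows; returns the chain's root unit
# (its id and linkage toward the residue the chain hangs from).
.emit_chain <- function(units, env) {
  ids <- integer(length(units))
  for (k in seq_along(units)) {
    u <- units[[k]]
    id <- env$next_id
    env$next_id <- env$next_id + 1L
    ids[k] <- id
    env$residues[[length(env$residues) + 1]] <- data.frame(
      id = id, name = u$name, anomer = u$anomer,
      ano_pos = u$child_pos,
      mods = paste(sort(u$mods), collapse = ";"))
    for (br in u$branches) {
      sub <- .emit_chain(br, env)
      env$edges[[length(env$edges) + 1]] <- data.frame(
        child = sub$id, parent = id,
        child_pos = sub$child_pos, parent_pos = sub$parent_pos)
    }
  }
  for (k in seq_len(length(units) - 1)) {
    u <- units[[k]]
    env$edges[[length(env$edges) + 1]] <- data.frame(
      child = ids[k], parent = ids[k + 1],
      child_pos = u$child_pos, parent_pos = u$parent_pos)
  }
  last <- units[[length(units)]]
  list(id = ids[length(units)], child_pos = last$child_pos,
       parent_pos = last$parent_pos)
}

#' Write a GlycanTree back to canonical condensed text
#'
#' Children of a residue are written child-first with branches sorted by
#' attachment position in descending order, which makes the text form
#' canonical: `parse_glycan(write_glycan(t))` reproduces `t`.
#'
#' @param tree a `glycan_tree`.
#' @return character scalar.
#' @export
write_glycan <- function(tree) {
  res <- tree$residues
  wr <- function(id) {
    r <- res[res$id == id, ]
    kids <- tree$edges[tree$edges$parent == id, , drop = FALSE]
    kids <- kids[order(-kids$parent_pos), , drop = FALSE]
    out <- ""
    if (nrow(kids) > 0) {
      piece <- function(e) {
        ch <- res[res$id == e$child, ]
        paste0(wr(e$child), "(", ch$anomer, e$child_pos, "-", e$parent_pos, ")")
      }
      out <- piece(kids[1, ])
      if (nrow(kids) > 1) {
        for (k in 2:nrow(kids)) {
          out <- paste0(out, "[", piece(kids[k, ]), "]")
        }
      }
    }
    mods <- .mod_list(r$mods)
    modstr <- if (length(mods) > 0) paste0(paste(sort(mods), collapse = "-"), "-") else ""
    paste0(out, modstr, r$name)
  }
  root <- res[res$id == tree$root, ]
  paste0(wr(tree$root), "(", root$anomer, root$ano_pos, "-")
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat(sprintf("<glycan_tree: %d residues, root %s> %s\n",
              nrow(x$residues),
              x$residues$name[x$residues$id == x$root],
              write_glycan(x)))
  invisible(x)
}

#' Number of residues in a glycan tree
#' @param tree a `glycan_tree`.
#' @return integer.
#' @export
n_residues <- function(tree) nrow(tree$residues)

# Children edges of a residue, ordered by attachment position.
.child_edges <- function(tree, id) {
  e <- tree$edges[tree$edges$parent == id, , drop = FALSE]
  e[order(e$parent_pos), , drop = FALSE]
}

#' Read a glycome file ("ID<TAB>sequence" per line)
#' @param path path to a tab-separated file with one glycan per line.
#' @return named list of `glycan_tree` objects (names are the IDs).
#' @export
read_glycome <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("glycome file line %d: expected 'ID<TAB>sequence'", k),
           call. = FALSE)
    }
    out[[parts[1]]] <- parse_glycan(parts[2])
  }
  out
}

#' Write a glycome list to a file
#' @param glycome named list of `glycan_tree` objects.
#' @param path output path.
#' @export
write_glycome <- function(glycome, path) {
  lines <- vapply(names(glycome),
                  function(id) paste0(id, "\t", write_glycan(glycome[[id]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
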