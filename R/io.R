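# Network serialization: canonical JSON schema plus a minimal BIF subset
# (discrete variables, table CPTs), the format benchmark networks circulate in.

#' Read a network from disk
#'
#' @param path file path.
#' @param format \code{"json"} (canonical schema) or \code{"bif"} (minimal
#'   subset: discrete variables, table-form probabilities).  Inferred from
#'   the file extension when missing.
#' @return a \code{bn_network}; node order follows the file.
#' @export
read_network <- function(path, format = NULL) {
  format <- infer_net_format(path, format)
  switch(format,
         json = read_network_json(path),
         bif = read_network_bif(path),
         stop("unknown format: ", format))
}

#' Write a network to disk
#'
#' @param net a \code{bn_network} with CPTs.
#' @param path file path.
#' @param format \code{"json"} or \code{"bif"}; inferred from the extension
#'   when missing.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  format <- infer_net_format(path, format)
  if (is.null(net$cpts)) stop("network has no CPTs; fit or attach them first")
  switch(format,
         json = write_network_json(net, path),
         bif = write_network_bif(net, path),
         stop("unknown format: ", format))
  invisible(path)
}

infer_net_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "bif")))
  if (grepl("\\.bif$", path, ignore.case = TRUE)) "bif" else "json"
}

# ---- JSON ------------------------------------------------------------------
# Schema: {"format":"k2bso-network","version":1,
#          "nodes":[{"name","states":[...],"parents":[...],"cpt":[[...]]}]}
# CPT rows are ordered by lexicographic parent configuration with the last
# parent fastest-varying.

read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$nodes)) stop("not a network file: missing 'nodes'")
  nodes <- vapply(doc$nodes, function(nd) nd$name, "")
  states <- lapply(doc$nodes, function(nd) as.character(unlist(nd$states)))
  names(states) <- nodes
  cards <- vapply(states, length, 1L)
  parents <- lapply(doc$nodes, function(nd) as.character(unlist(nd$parents)))
  names(parents) <- nodes
  cpts <- lapply(doc$nodes, function(nd) {
    do.call(rbind, lapply(nd$cpt, function(row) as.numeric(unlist(row))))
  })
  names(cpts) <- nodes
  bn_network(nodes, cards, parents, cpts, states = states)
}

write_network_json <- function(net, path) {
  nodes <- lapply(net$nodes, function(v) {
    list(name = jsonlite::unbox(v),
         states = net$states[[v]],
         parents = net$parent_sets[[v]],
         cpt = apply(net$cpts[[v]], 1L, identity, simplify = FALSE))
  })
  doc <- list(format = jsonlite::unbox("k2bso-network"),
              version = jsonlite::unbox(1L),
              nodes = nodes)
  jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
}

# ---- BIF subset ------------------------------------------------------------
# Supports: network <name> { }, variable blocks with
# "type discrete [ r ] { a, b };" and probability blocks in table form or
# with per-parent-configuration rows "(a, b) p1, p2;".

read_network_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)           # strip line comments
  nodes <- character(0); states <- list()
  var_pat <- "variable\\s+([^\\s{]+)\\s*\\{[^}]*type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}\\s*;[^}]*\\}"
  m <- gregexpr(var_pat, txt, perl = TRUE)
  vm <- regmatches(txt, m)[[1L]]
  for (blk in vm) {
    name <- sub(var_pat, "\\1", blk, perl = TRUE)
    r <- as.integer(sub(var_pat, "\\2", blk, perl = TRUE))
    sts <- trimws(strsplit(sub(var_pat, "\\3", blk, perl = TRUE), ",")[[1L]])
    if (length(sts) != r) stop("BIF: state count mismatch for ", name)
    nodes <- c(nodes, name)
    states[[name]] <- sts
  }
  if (!length(nodes)) stop("BIF: no variable blocks found")
  cards <- vapply(states, length, 1L)
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  cpts <- stats::setNames(vector("list", length(nodes)), nodes)
  prob_pat <- "probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}"
  pm <- regmatches(txt, gregexpr(prob_pat, txt, perl = TRUE))[[1L]]
  for (blk in pm) {
    head <- sub(prob_pat, "\\1", blk, perl = TRUE)
    body <- sub(prob_pat, "\\2", blk, perl = TRUE)
    parts <- strsplit(head, "\\|")[[1L]]
    child <- trimws(parts[[1L]])
    pa <- if (length(parts) > 1L) {
      trimws(strsplit(parts[[2L]], ",")[[1L]])
    } else character(0)
    if (!child %in% nodes) stop("BIF: probability for unknown variable ", child)
    parents[[child]] <- pa
    r <- cards[[child]]
    if (!length(pa)) {
      vals <- sub(".*table", "", body)
      vals <- as.numeric(trimws(strsplit(gsub(";", "", vals), ",")[[1L]]))
      if (length(vals) != r) stop("BIF: table length mismatch for ", child)
      cpts[[child]] <- matrix(vals, 1L, r)
    } else {
      q <- prod(cards[pa])
      cpt <- matrix(NA_real_, q, r)
      row_pat <- "\\(([^)]*)\\)([^;]*);"
      rows <- regmatches(body, gregexpr(row_pat, body, perl = TRUE))[[1L]]
      for (rw in rows) {
        cfg <- trimws(strsplit(sub(row_pat, "\\1", rw, perl = TRUE), ",")[[1L]])
        vals <- as.numeric(trimws(strsplit(sub(row_pat, "\\2", rw, perl = TRUE),
                                           ",")[[1L]]))
        idx0 <- mapply(function(s, p) match(s, states[[p]]) - 1L, cfg, pa)
        if (anyNA(idx0)) stop("BIF: unknown parent state in row for ", child)
        j <- config_index(as.integer(idx0), cards[pa])
        cpt[j, ] <- vals
      }
      if (anyNA(cpt)) stop("BIF: missing parent configuration rows for ", child)
      cpts[[child]] <- cpt
    }
  }
  for (v in nodes) if (is.null(parents[[v]])) parents[[v]] <- character(0)
  bn_network(nodes, cards, parents, cpts, states = states)
}

write_network_bif <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("network unknown {\n}", con)
  for (v in net$nodes) {
    writeLines(sprintf("variable %s {\n  type discrete [ %d ] { %s };\n}",
                       v, net$cardinalities[[v]],
                       paste(net$states[[v]], collapse = ", ")), con)
  }
  for (v in net$nodes) {
    pa <- net$parent_sets[[v]]
    cpt <- net$cpts[[v]]
    if (!length(pa)) {
      writeLines(sprintf("probability ( %s ) {\n  table %s;\n}", v,
                         paste(format(cpt[1L, ], digits = 17),
                               collapse = ", ")), con)
    } else {
      lines <- sprintf("probability ( %s | %s ) {", v, paste(pa, collapse = ", "))
      cards <- net$cardinalities[pa]
      for (j in seq_len(nrow(cpt))) {
        cfg0 <- config_unindex(j, cards)
        labs <- mapply(function(s, p) net$states[[p]][s + 1L], cfg0, pa)
        lines <- c(lines, sprintf("  (%s) %s;", paste(labs, collapse = ", "),
                                  paste(format(cpt[j, ], digits = 17),
                                        collapse = ", ")))
      }
      writeLines(c(lines, "}"), con)
    }
  }
}

# 1-based row index of a parent configuration; last parent fastest-varying.
config_index <- function(states0, cards) {
  j <- 0L
  for (i in seq_along(cards)) j <- j * cards[[i]] + states0[[i]]
  j + 1L
}

# inverse of config_index: 0-based states for row j (1-based)
config_unindex <- function(j, cards) {
  j <- j - 1L
  out <- integer(length(cards))
  for (i in rev(seq_along(cards))) {
    out[[i]] <- j %% cards[[i]]
    j <- j %/% cards[[i]]
  }
  out
}
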