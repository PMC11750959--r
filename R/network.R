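#' Construct a stoichiometric reaction network
#'
#' A network holds a set of metabolites, a set of reactions with flux
#' bounds, and the stoichiometric matrix `S` (rows = metabolites, columns =
#' reactions). Internal metabolites are subject to the steady-state
#' constraint `S_int %*% v = 0`; boundary (external) metabolites are not.
#'
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `is_internal` (default TRUE).
#' @param reactions data.frame with columns `id` and optionally
#'   `reversible` (default FALSE), `lb`, `ub` (flux bounds in
#'   mmol/gDW/day; defaults 0 or -1000 to 1000 depending on reversibility).
#' @param stoichiometry named list (one element per reaction id) of named
#'   numeric vectors mapping metabolite id to signed coefficient
#'   (negative = consumed, positive = produced).
#' @return object of class `reaction_network` with elements `metabolites`,
#'   `reactions`, `stoichiometry` and the dense matrix `S`.
#' @export
#' @examples
#' net <- reaction_network(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("upt", "conv", "exp")),
#'   stoichiometry = list(upt = c(A = 1), conv = c(A = -1, B = 1),
#'                        exp = c(B = -1)))
#' net$S
reaction_network <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"is_internal" %in% names(metabolites)) metabolites$is_internal <- TRUE
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  if (!"lb" %in% names(reactions))
    reactions$lb <- ifelse(reactions$reversible, -1000, 0)
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000

  if (nrow(metabolites) == 0L || nrow(reactions) == 0L)
    stop("empty network: need at least one metabolite and one reaction")
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (!all(reactions$id %in% names(stoichiometry)))
    stop("missing stoichiometry for reaction(s): ",
         paste(setdiff(reactions$id, names(stoichiometry)), collapse = ", "))
  stoichiometry <- stoichiometry[reactions$id]
  for (rid in reactions$id) {
    sto <- stoichiometry[[rid]]
    if (length(sto) == 0L)
      stop("reaction '", rid, "' has empty stoichiometry")
    unknown <- setdiff(names(sto), metabolites$id)
    if (length(unknown) > 0L)
      stop("unknown metabolite '", unknown[1L], "' in reaction '", rid, "'")
  }
  bad <- which(!reactions$reversible & reactions$lb < 0)
  if (length(bad) > 0L)
    stop("irreversible reaction with negative lower bound: ",
         paste(reactions$id[bad], collapse = ", "))
  if (any(reactions$lb > reactions$ub))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  if (!any(metabolites$is_internal))
    stop("network needs at least one internal metabolite")

  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        stoichiometry = stoichiometry),
                   class = "reaction_network")
  net$S <- build_stoichiometric_matrix(net)
  net
}

#' Build the stoichiometric matrix of a network
#'
#' Rows are ordered by metabolite declaration, columns by reaction
#' declaration; entry `(i, j)` is the signed coefficient of metabolite `i`
#' in reaction `j` (0 if absent).
#'
#' @param network a `reaction_network` (the `S` element is ignored; the
#'   matrix is rebuilt from the stoichiometry maps).
#' @return dense numeric matrix with metabolite ids as rownames and
#'   reaction ids as colnames.
#' @export
build_stoichiometric_matrix <- function(network) {
  mets <- network$metabolites$id
  rxns <- network$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    sto <- network$stoichiometry[[rxns[j]]]
    S[names(sto), j] <- as.numeric(sto)
  }
  S
}

#' Internal-metabolite submatrix of the stoichiometric matrix
#'
#' The rows of `S` for metabolites flagged internal; these are the
#' species held at steady state (`S_int %*% v = 0`) by
#' [solve_snapshot_fluxes()].
#' @param network a [reaction_network()].
#' @return numeric matrix (internal metabolites x reactions).
#' @export
s_internal <- function(network) {
  network$S[network$metabolites$is_internal, , drop = FALSE]
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", nrow(x$metabolites), "metabolites (",
      sum(x$metabolites$is_internal), "internal ),",
      nrow(x$reactions), "reactions\n")
  invisible(x)
}

#' Load a reaction network from a file
#'
#' Two formats are supported. `"reaction_table"` is a TSV with columns
#' `id`, `equation`, `reversible` (0/1), `lb`, `ub`; lines starting with
#' `#` are comments, except a directive line `#! external: id1 id2 ...`
#' that marks metabolites as boundary species. Equations look like
#' `"2 A + B -> C"`; an empty side denotes exchange with the environment
#' (e.g. `"-> GLC"` for an uptake). `"sbml"` reads a subset of SBML Level 3
#' core: species (`boundaryCondition` marks external metabolites),
#' reactions with reactant/product stoichiometries and the `reversible`
#' flag. Kinetic laws and flux-bound annotations are ignored; reversible
#' reactions get bounds (-1000, 1000), irreversible (0, 1000).
#'
#' @param source path to the file (or, for `reaction_table`, a character
#'   vector of lines).
#' @param format `"reaction_table"` or `"sbml"`.
#' @return a [reaction_network()].
#' @export
load_network <- function(source, format = c("reaction_table", "sbml")) {
  format <- match.arg(format)
  switch(format,
         reaction_table = load_reaction_table(source),
         sbml = load_sbml(source))
}

parse_equation <- function(eq) {
  parts <- strsplit(eq, "->", fixed = TRUE)[[1L]]
  if (length(parts) > 2L) stop("malformed equation: ", eq)
  reversible_arrow <- grepl("<->", eq, fixed = TRUE)
  lhs <- sub("<$", "", trimws(parts[1L]))
  rhs <- if (length(parts) == 2L) trimws(parts[2L]) else ""
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0L))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    out <- numeric(0L)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1L]]
      if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1L]))
        if (is.na(coef)) stop("malformed term '", tm, "' in equation: ", eq)
        id <- toks[2L]
      } else if (length(toks) == 1L) {
        coef <- 1; id <- toks[1L]
      } else stop("malformed term '", tm, "' in equation: ", eq)
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  sto <- c(parse_side(lhs, -1), parse_side(rhs, +1))
  sto <- tapply(sto, names(sto), sum)
  sto <- sto[sto != 0]
  list(stoichiometry = stats::setNames(as.numeric(sto), names(sto)),
       reversible = reversible_arrow)
}

load_reaction_table <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  external <- character(0L)
  dir_idx <- grep("^#!\\s*external:", lines)
  for (i in dir_idx) {
    external <- c(external,
                  strsplit(trimws(sub("^#!\\s*external:", "", lines[i])), "\\s+")[[1L]])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty network: no reaction rows found")
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("id", "equation")
  if (!all(need %in% names(tab)))
    stop("reaction table needs columns: ", paste(need, collapse = ", "))
  if (!"reversible" %in% names(tab)) tab$reversible <- 0L
  sto <- list(); rev <- logical(nrow(tab))
  met_ids <- character(0L)
  for (i in seq_len(nrow(tab))) {
    p <- parse_equation(tab$equation[i])
    sto[[tab$id[i]]] <- p$stoichiometry
    rev[i] <- p$reversible || as.logical(tab$reversible[i])
    met_ids <- union(met_ids, names(p$stoichiometry))
  }
  reactions <- data.frame(id = tab$id, reversible = rev,
                          stringsAsFactors = FALSE)
  if ("lb" %in% names(tab)) reactions$lb <- tab$lb
  if ("ub" %in% names(tab)) reactions$ub <- tab$ub
  metabolites <- data.frame(id = met_ids,
                            is_internal = !(met_ids %in% external),
                            stringsAsFactors = FALSE)
  reaction_network(metabolites, reactions, sto)
}

#' Write a network as a reaction-table TSV
#'
#' Inverse of the `reaction_table` reader; round-trips the stoichiometric
#' matrix exactly.
#'
#' @param network a `reaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(network, path) {
  fmt_side <- function(sto, keep) {
    sel <- sto[keep(sto)]
    if (length(sel) == 0L) return("")
    paste(ifelse(abs(sel) == 1, names(sel),
                 paste(format(abs(sel), trim = TRUE), names(sel))),
          collapse = " + ")
  }
  eqs <- vapply(network$reactions$id, function(rid) {
    sto <- network$stoichiometry[[rid]]
    paste(fmt_side(sto, function(s) s < 0), "->", fmt_side(sto, function(s) s > 0))
  }, character(1L))
  tab <- data.frame(id = network$reactions$id, equation = trimws(eqs),
                    reversible = as.integer(network$reactions$reversible),
                    lb = network$reactions$lb, ub = network$reactions$ub)
  header <- character(0L)
  ext <- network$metabolites$id[!network$metabolites$is_internal]
  if (length(ext) > 0L)
    header <- paste("#! external:", paste(ext, collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0L) stop("empty network: no species in SBML file")
  met_id <- xml2::xml_attr(sp, "id")
  boundary <- tolower(ifelse(is.na(xml2::xml_attr(sp, "boundaryCondition")),
                             "false", xml2::xml_attr(sp, "boundaryCondition")))
  metabolites <- data.frame(id = met_id,
                            name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                                          met_id, xml2::xml_attr(sp, "name")),
                            is_internal = boundary != "true",
                            stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("empty network: no reactions in SBML file")
  sto <- list()
  rid <- xml2::xml_attr(rx, "id")
  rev <- tolower(ifelse(is.na(xml2::xml_attr(rx, "reversible")), "true",
                        xml2::xml_attr(rx, "reversible"))) == "true"
  for (i in seq_along(rx)) {
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx[[i]], xp)
      if (length(nodes) == 0L) return(numeric(0L))
      coef <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, "stoichiometry")))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    v <- c(refs("./listOfReactants/speciesReference", -1),
           refs("./listOfProducts/speciesReference", +1))
    v <- tapply(v, names(v), sum)
    sto[[rid[i]]] <- stats::setNames(as.numeric(v), names(v))
  }
  # drop coefficients on boundary species? no: they are kept in S but the
  # steady-state constraint only covers internal rows
  reactions <- data.frame(id = rid, reversible = rev,
                          lb = ifelse(rev, -1000, 0), ub = 1000,
                          stringsAsFactors = FALSE)
  reaction_network(metabolites, reactions, sto)
}
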