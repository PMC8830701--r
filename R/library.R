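# Ansatz reaction libraries: construction, template-driven enumeration,
# stoichiometric matrices, plain-text serialization, and named presets.

#' Create an ansatz reaction library
#'
#' An ordered, duplicate-free list of candidate mass-action reactions over a
#' common species set, together with its complete stoichiometric matrix.
#' Rate indices are positional: reaction `d` corresponds to rate `k[d]` and to
#' row `d` of the stoichiometric matrix.
#'
#' @param species a [species_set()].
#' @param reactions list of `crn_reaction` objects (or reaction strings, which
#'   are parsed against `species`).
#' @return an object of class `crn_library` with elements `species`,
#'   `reactions`, `stoich` (D x N net-change matrix) and `rcount`
#'   (D x N reactant multiplicity matrix).
#' @export
ansatz_library <- function(species, reactions) {
  if (length(reactions) < 1L) stop("library must contain at least one reaction")
  reactions <- lapply(reactions, function(r) {
    if (is.character(r)) parse_reaction(r, species) else r
  })
  keys <- vapply(reactions, .reaction_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate reaction(s) in library: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  }
  for (r in reactions) {
    if (!identical(r$species$names, species$names)) {
      stop("reaction species set does not match library species set")
    }
  }
  lib <- structure(list(species = species, reactions = reactions),
                   class = "crn_library")
  lib$stoich <- build_stoichiometric_matrix(lib)
  lib$rcount <- .reactant_count_matrix(lib)
  lib
}

#' Number of reactions in a library
#' @param x a `crn_library`.
#' @return integer count D.
#' @export
n_reactions <- function(x) length(x$reactions)

#' @export
print.crn_library <- function(x, ...) {
  cat("Ansatz library: ", n_reactions(x), " reactions over ",
      length(x$species$names), " species (",
      paste(x$species$names, collapse = ", "), ")\n", sep = "")
  strs <- vapply(x$reactions, format, character(1))
  for (i in seq_along(strs)) cat(sprintf("  [%d] %s\n", i, strs[i]))
  invisible(x)
}

.side_count_row <- function(m, species) {
  v <- setNames(numeric(length(species$names)), species$names)
  v[names(m)] <- m
  v
}

#' Build the complete stoichiometric matrix of a library
#'
#' Row `d` holds the net species change (product counts minus reactant counts)
#' of reaction `d`; entries lie in `{-2,...,2}`. The reaction-rate equations
#' are `dX/dt = t(S) %*% (k * f(X))` with `S` this matrix.
#'
#' @param library a `crn_library` (or a bare list with `species`, `reactions`).
#' @return integer matrix with D rows and N columns (named).
#' @export
build_stoichiometric_matrix <- function(library) {
  sp <- library$species
  rows <- t(vapply(library$reactions, function(r) {
    .side_count_row(r$products, sp) - .side_count_row(r$reactants, sp)
  }, numeric(length(sp$names))))
  rows <- matrix(as.integer(rows), nrow = length(library$reactions),
                 dimnames = list(NULL, sp$names))
  rows
}

.reactant_count_matrix <- function(library) {
  sp <- library$species
  rows <- t(vapply(library$reactions, function(r) {
    .side_count_row(r$reactants, sp)
  }, numeric(length(sp$names))))
  matrix(as.integer(rows), nrow = length(library$reactions),
         dimnames = list(NULL, sp$names))
}

#' Reaction strings of a library
#' @param library a `crn_library`.
#' @return character vector of length D.
#' @export
reaction_strings <- function(library) {
  vapply(library$reactions, format, character(1))
}

# ---- template-driven enumeration -------------------------------------------

#' Named reaction-template catalogue
#'
#' Templates are reaction strings over placeholder species `A`, `B`, `C`, `D`;
#' each template is instantiated over every assignment of distinct library
#' species to its placeholders. Named groups bundle common template families.
#'
#' @return named list mapping group names to character vectors of templates.
#' @export
template_catalogue <- function() {
  list(
    decay        = "A -> 0",
    birth        = "0 -> A",
    conversion   = "A -> B",
    autocatalysis = "A -> 2A",
    splitting    = "A -> 2B",
    pair_decay   = "2A -> 0",
    dimer_decay  = "2A -> A",
    dimerization = "2A -> B",
    predation    = "A + B -> 2A",
    catalytic_decay = "A + B -> A",
    binding      = "A + B -> C",
    dissociation = "A -> B + C",
    catalysis    = "A -> A + B",
    exchange     = "A + B -> C + D"
  )
}

#' Enumerate an ansatz library from templates
#'
#' Instantiates every selected template over all assignments of distinct
#' species to its placeholders, deduplicates, and returns a library with
#' deterministic ordering: template-major, then lexicographic in the assigned
#' species (placeholder order `A`, `B`, `C`, `D`).
#'
#' @param species a [species_set()].
#' @param templates character vector of template strings over placeholders
#'   `A`-`D` (e.g. `"A + B -> 2A"`) and/or group names from
#'   [template_catalogue()] (e.g. `"decay"`).
#' @return a `crn_library`.
#' @export
enumerate_ansatz <- function(species, templates) {
  if (length(templates) < 1L) stop("template set must not be empty")
  cat_ <- template_catalogue()
  expanded <- unlist(lapply(templates, function(tm) {
    if (tm %in% names(cat_)) cat_[[tm]] else tm
  }), use.names = FALSE)
  placeholders <- c("A", "B", "C", "D")
  ph_set <- species_set(placeholders)
  out <- list()
  keys <- character(0)
  for (tm in expanded) {
    tpl <- parse_reaction(tm, ph_set)
    used <- intersect(placeholders,
                      union(names(tpl$reactants), names(tpl$products)))
    n_ph <- length(used)
    if (n_ph > length(species$names)) next  # no distinct assignment exists
    for (row in .ordered_tuples(species$names, n_ph)) {
      map <- setNames(row, used)
      r <- setNames(as.integer(tpl$reactants), unname(map[names(tpl$reactants)]))
      p <- setNames(as.integer(tpl$products), unname(map[names(tpl$products)]))
      rx <- tryCatch(reaction(r, p, species), error = function(e) NULL)
      if (is.null(rx)) next  # e.g. identity instantiation of a symmetric template
      key <- .reaction_key(rx)
      if (!key %in% keys) {
        keys <- c(keys, key)
        out[[length(out) + 1L]] <- rx
      }
    }
  }
  if (length(out) == 0L) {
    stop("selected templates produce no reactions over this species set")
  }
  ansatz_library(species, out)
}

# all ordered tuples of n distinct species, lexicographic in placeholder order
.ordered_tuples <- function(names, n) {
  if (n == 0L) return(list(character(0)))
  rec <- function(chosen) {
    if (length(chosen) == n) return(list(chosen))
    rest <- setdiff(names, chosen)
    do.call(c, lapply(rest, function(s) rec(c(chosen, s))))
  }
  rec(character(0))
}

# ---- plain-text serialization ----------------------------------------------

#' Write a reaction library to a plain-text file
#'
#' Format: a header line `species: A, B, C` followed by one reaction string
#' per line; `#` starts a comment.
#'
#' @param library a `crn_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path) {
  lines <- c(paste0("species: ", paste(library$species$names, collapse = ", ")),
             reaction_strings(library))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reaction library from a plain-text file
#'
#' @param path file as written by [save_library()].
#' @return a `crn_library`.
#' @export
load_library <- function(path) {
  raw <- readLines(path)
  stripped <- sub("#.*$", "", raw)
  keep <- which(trimws(stripped) != "")
  if (length(keep) == 0L) stop("empty library file: ", path)
  first <- trimws(stripped[keep[1]])
  if (!grepl("^species:", first)) {
    stop("library file must start with a 'species:' header line: ", path)
  }
  sp <- species_set(trimws(strsplit(sub("^species:", "", first), ",")[[1]]))
  rx_lines <- keep[-1]
  if (length(rx_lines) == 0L) stop("library file contains no reactions: ", path)
  reactions <- list()
  keys <- character(0)
  for (ln in rx_lines) {
    rx <- tryCatch(parse_reaction(trimws(stripped[ln]), sp),
                   error = function(e) {
                     stop("line ", ln, ": ", conditionMessage(e), call. = FALSE)
                   })
    key <- .reaction_key(rx)
    if (key %in% keys) {
      stop("line ", ln, ": duplicate reaction '", key, "'", call. = FALSE)
    }
    keys <- c(keys, key)
    reactions[[length(reactions) + 1L]] <- rx
  }
  ansatz_library(sp, reactions)
}

# ---- presets ----------------------------------------------------------------

#' Named candidate-library presets
#'
#' * `"lv-table1"`: the 16-reaction Lotka-Volterra candidate set over species
#'   `(P, Y)` (predator, prey). The published table labels the prey `X` and
#'   contains an apparent duplicate degradation row; here the row carrying the
#'   true rate 0.3 is read as predator death `P -> 0`, which makes all 16
#'   rows distinct and embeds the 3-reaction generating system
#'   (`Y -> 2 Y`, `P + Y -> 2 P`, `P -> 0`).
#' * `"autoreg-true"`: the 8-reaction prokaryotic auto-regulation network over
#'   `(g, P2, gP2, r, P)`.
#' * `"autoreg-reduced"`: a 41-reaction candidate set for the auto-regulation
#'   system: the 8 true reactions first, then decays, first-order
#'   conversions, pair decays and autocatalytic births.
#'
#' @param name preset name.
#' @return a `crn_library`.
#' @export
library_preset <- function(name) {
  switch(name,
    "lv-table1" = {
      sp <- species_set(c("P", "Y"))
      ansatz_library(sp, c(
        "2 Y -> 0",       # [1]
        "2 P -> 0",       # [2]
        "Y -> 2 Y",       # [3] true k = 1.0 (prey birth)
        "P + Y -> 2 P",   # [4] true k = 0.01 (predation)
        "P -> 0",         # [5] true k = 0.3 (predator death)
        "P + Y -> 2 Y",   # [6]
        "Y -> 0",         # [7]
        "2 P -> P",       # [8]
        "P -> 2 P",       # [9]
        "2 Y -> Y",       # [10]
        "P + Y -> Y",     # [11]
        "P + Y -> P",     # [12]
        "2 Y -> P",       # [13]
        "Y -> P",         # [14]
        "P -> Y",         # [15]
        "Y -> 2 P"        # [16]
      ))
    },
    "autoreg-true" = ansatz_library(.autoreg_species(), .autoreg_true_strings()),
    "autoreg-reduced" = {
      sp <- .autoreg_species()
      base <- .autoreg_true_strings()
      extra <- enumerate_ansatz(sp, c("decay", "conversion", "pair_decay",
                                      "autocatalysis"))
      strs <- c(base, setdiff(reaction_strings(extra), base))
      ansatz_library(sp, strs)
    },
    stop("unknown library preset: ", name)
  )
}

.autoreg_species <- function() species_set(c("g", "P2", "gP2", "r", "P"))

.autoreg_true_strings <- function() {
  c("g + P2 -> gP2",   # repression,      k1 = 0.5
    "gP2 -> g + P2",   # de-repression,   k2 = 1
    "g -> g + r",      # transcription,   k3 = 0.15
    "r -> r + P",      # translation,     k4 = 1
    "2 P -> P2",       # dimerization,    k5 = 0.5
    "P2 -> 2 P",       # dissociation,    k6 = 0.5
    "r -> 0",          # mRNA decay,      k7 = 1.5
    "P -> 0")          # protein decay,   k8 = 0.3
}
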