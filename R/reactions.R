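# Species sets, single reactions, and the reaction-string grammar:
#   side "->" side ;  side = "0" | term ("+" term)* ;  term = [coefficient] species
# with coefficients in {1, 2} and total multiplicity <= 2 per side.

#' Create a species set
#'
#' An ordered set of species identifiers. The order is fixed and used for all
#' matrix columns (stoichiometry, trajectories, observation maps).
#'
#' @param names character vector of unique, nonempty species identifiers.
#'   Identifiers must start with a letter and may contain letters, digits and
#'   underscores.
#' @return an object of class `crn_species`.
#' @export
species_set <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("species set must contain at least one species")
  if (anyDuplicated(names)) stop("species names must be unique")
  if (!all(grepl("^[A-Za-z][A-Za-z0-9_]*$", names))) {
    stop("invalid species identifier(s): ",
         paste(names[!grepl("^[A-Za-z][A-Za-z0-9_]*$", names)], collapse = ", "))
  }
  structure(list(names = names), class = "crn_species")
}

#' @export
print.crn_species <- function(x, ...) {
  cat("Species set (", length(x$names), "): ", paste(x$names, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# multiset over species as a named integer vector (only positive counts kept)
.as_multiset <- function(counts, species) {
  out <- setNames(integer(length(species$names)), species$names)
  for (nm in names(counts)) {
    if (!nm %in% species$names) stop("unknown species: ", nm)
    out[nm] <- out[nm] + as.integer(counts[nm])
  }
  out[out > 0L]
}

#' Create a mass-action reaction
#'
#' Reactant and product sides are multisets over the species set with total
#' multiplicity at most 2 (up to second-order mass-action kinetics). A
#' reaction must have a non-zero net stoichiometric change: reactions whose
#' reactant and product multisets coincide are unidentifiable and rejected.
#'
#' @param reactants,products named integer vectors of species counts (may be
#'   empty for zero-order / pure-degradation sides).
#' @param species a [species_set()].
#' @param label optional text label.
#' @return an object of class `crn_reaction`.
#' @export
reaction <- function(reactants, products, species, label = NULL) {
  r <- .as_multiset(reactants, species)
  p <- .as_multiset(products, species)
  if (sum(r) > 2L) stop("reactant order exceeds 2: ", .format_side(r))
  if (sum(p) > 2L) stop("product order exceeds 2: ", .format_side(p))
  full <- function(m) {
    v <- setNames(integer(length(species$names)), species$names)
    v[names(m)] <- m
    v
  }
  if (identical(full(r), full(p))) {
    stop("reaction has no net stoichiometric change: ",
         .format_side(r), " -> ", .format_side(p))
  }
  structure(list(reactants = r, products = p, species = species,
                 label = label),
            class = "crn_reaction")
}

.format_side <- function(m) {
  if (length(m) == 0L) return("0")
  paste(ifelse(m > 1L, paste(m, names(m)), names(m)), collapse = " + ")
}

#' Format a reaction as a string
#'
#' Inverse of [parse_reaction()]; terms are printed in species-set order with
#' explicit coefficient 2 where needed, e.g. `"P + Y -> 2 P"`.
#'
#' @param x a `crn_reaction`.
#' @param ... ignored.
#' @return a character scalar.
#' @export
format.crn_reaction <- function(x, ...) {
  ord <- function(m) m[order(match(names(m), x$species$names))]
  paste(.format_side(ord(x$reactants)), "->", .format_side(ord(x$products)))
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.parse_side <- function(text, species, context) {
  text <- trimws(text)
  if (text == "0") return(integer(0))
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  counts <- integer(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)?[ ]*([A-Za-z][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(m) == 0L) stop("cannot parse term '", tm, "' in ", context)
    cf <- if (m[2] == "") 1L else as.integer(m[2])
    if (!cf %in% c(1L, 2L)) stop("coefficient must be 1 or 2 in ", context)
    sp <- m[3]
    if (!sp %in% species$names) stop("unknown species '", sp, "' in ", context)
    counts[sp] <- if (sp %in% names(counts)) counts[sp] + cf else cf
  }
  counts
}

#' Parse a reaction string
#'
#' @param text reaction string such as `"Y -> 2 Y"`, `"P + Y -> 2P"` or
#'   `"X -> 0"` (`0` denotes the empty side).
#' @param species a [species_set()].
#' @param label optional label attached to the reaction.
#' @return a `crn_reaction`.
#' @export
parse_reaction <- function(text, species, label = NULL) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction must contain exactly one '->': ", text)
  reaction(.parse_side(sides[1], species, sQuote(text)),
           .parse_side(sides[2], species, sQuote(text)),
           species, label = label)
}

# canonical dedup key independent of term order
.reaction_key <- function(rx) {
  ord <- function(m) m[order(match(names(m), rx$species$names))]
  paste(.format_side(ord(rx$reactants)), "->", .format_side(ord(rx$products)))
}
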