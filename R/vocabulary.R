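# Controlled vocabulary of interaction types.
#
# Knowledgebase-derived disease networks carry typed edges; the closed default
# set below covers the interaction categories reported for such networks
# (association dominating, plus regulatory, physical and chemical relations).
# The registry is extensible so that additional knowledgebase-specific types
# can be admitted without patching the package.

.vocab <- new.env(parent = emptyenv())

.default_itypes <- c(
  "association"               = FALSE,
  "genetic-regulation"        = TRUE,
  "expression-upregulation"   = TRUE,
  "expression-downregulation" = TRUE,
  "activity-regulation"       = TRUE,
  "degradation-regulation"    = TRUE,
  "transport-regulation"      = TRUE,
  "protein-protein"           = FALSE,
  "expression"                = TRUE,
  "co-expression"             = FALSE,
  "chemical-transformation"   = TRUE,
  "treatment"                 = TRUE
)

# itypes whose edges make up the genetic regulatory subnetwork
.regulatory_itypes <- c("genetic-regulation",
                        "expression-upregulation",
                        "expression-downregulation")

.vocab$itypes <- .default_itypes

#' Interaction type vocabulary
#'
#' `interaction_types()` lists the registered interaction types;
#' `register_interaction_type()` admits a new type (with its default edge
#' directionality); `reset_interaction_types()` restores the built-in set.
#' Regulation-like types are directed by default; association, protein-protein
#' and co-expression edges are undirected.
#'
#' @param type character scalar, a new interaction type name.
#' @param directed logical scalar, whether edges of this type are directed
#'   by default.
#' @return `interaction_types()` returns a character vector of type names.
#' @export
interaction_types <- function() names(.vocab$itypes)

#' @rdname interaction_types
#' @export
register_interaction_type <- function(type, directed = TRUE) {
  stopifnot(is.character(type), length(type) == 1L, nzchar(type),
            is.logical(directed), length(directed) == 1L)
  v <- .vocab$itypes
  v[type] <- directed
  .vocab$itypes <- v
  invisible(type)
}

#' @rdname interaction_types
#' @export
reset_interaction_types <- function() {
  .vocab$itypes <- .default_itypes
  invisible(names(.default_itypes))
}

itype_directed_default <- function(itype) {
  unname(.vocab$itypes[itype])
}

check_itypes <- function(itype) {
  bad <- setdiff(unique(itype), interaction_types())
  if (length(bad) > 0L) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         " (see interaction_types(); register_interaction_type() to extend)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Interaction types forming the genetic regulatory subnetwork
#'
#' @return character vector of the regulatory interaction types
#'   (expression regulation and its up-/down-regulation variants).
#' @export
regulatory_itypes <- function() .regulatory_itypes
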