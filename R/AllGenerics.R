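#' @title Accessors for the core classes
#' @description `nTaxa()` gives the number of species/tips; `tipLabels()` the
#'   species names; `nReticulations()` the number of reticulation events
#'   retained in a network; `networkDepth()` the root-to-tip time; `trees()`
#'   the list of trees in a profile; `reticulations()` the routing table.
#' @param x a [SpeciesNetwork-class] or [TreeProfile-class].
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))
#' @rdname accessors
#' @export
setGeneric("nReticulations", function(x) standardGeneric("nReticulations"))
#' @rdname accessors
#' @export
setGeneric("networkDepth", function(x) standardGeneric("networkDepth"))
#' @rdname accessors
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))
#' @rdname accessors
#' @export
setGeneric("reticulations", function(x) standardGeneric("reticulations"))

#' @rdname accessors
#' @export
setMethod("nTaxa", "SpeciesNetwork", function(x) length(x@tips))
#' @rdname accessors
#' @export
setMethod("nTaxa", "TreeProfile", function(x) length(x@taxa))
#' @rdname accessors
#' @export
setMethod("tipLabels", "SpeciesNetwork", function(x) x@tipLabels)
#' @rdname accessors
#' @export
setMethod("tipLabels", "TreeProfile", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("nReticulations", "SpeciesNetwork",
          function(x) nrow(x@reticulations))
#' @rdname accessors
#' @export
setMethod("networkDepth", "SpeciesNetwork", function(x) x@depth)
#' @rdname accessors
#' @export
setMethod("trees", "TreeProfile", function(x) x@trees)
#' @rdname accessors
#' @export
setMethod("reticulations", "SpeciesNetwork", function(x) x@reticulations)

#' @describeIn TreeProfile-class number of trees in the profile.
#' @param x a `TreeProfile`.
#' @export
setMethod("length", "TreeProfile", function(x) length(x@trees))

#' @describeIn TreeProfile-class extract one tree.
#' @param i index.
#' @param j,... unused.
#' @export
setMethod("[[", "TreeProfile", function(x, i, j, ...) x@trees[[i]])

setMethod("show", "SpeciesNetwork", function(object) {
  r <- object@reticulations
  cat(sprintf("SpeciesNetwork: %d taxa, depth %.4g, %d reticulation(s)\n",
              length(object@tips), object@depth, nrow(r)))
  if (nrow(r))
    cat(sprintf("  %d hybrid speciation(s), %d introgression(s)\n",
                sum(r$type == "hybrid"), sum(r$type == "introgression")))
  cat("  tips:", paste(head(object@tipLabels, 8), collapse = ", "),
      if (length(object@tipLabels) > 8) "..." else "", "\n")
  if (!is.null(object@metadata$haltReason))
    cat("  halted on:", object@metadata$haltReason, "\n")
  invisible(object)
})

setMethod("show", "TreeProfile", function(object) {
  cat(sprintf("TreeProfile: %d tree(s) on %d taxa\n",
              length(object@trees), length(object@taxa)))
  invisible(object)
})

setMethod("show", "RateSet", function(object) {
  cat(sprintf(
    "RateSet: lambdaS=%g lambdaH=%g lambdaI=%g lambdaC=%g threshold=%g\n",
    object@lambdaS, object@lambdaH, object@lambdaI, object@lambdaC,
    object@threshold))
  invisible(object)
})

setMethod("show", "EpochSchedule", function(object) {
  cat(sprintf("EpochSchedule: %d epoch(s), success function '%s'\n",
              length(object@epochs), object@successKind))
  invisible(object)
})
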