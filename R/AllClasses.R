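#' @import methods
NULL

#' FundusImage: an RGB fundus-like image with optional ground-truth masks
#'
#' Container for one retinal fundus (or synthetic fundus-like) image together
#' with optional per-pixel optic-disc and optic-cup ground-truth masks. The
#' cup is anatomically contained in the disc, and the validity method enforces
#' `cupMask <= discMask` pixelwise whenever both masks are present.
#'
#' @slot pixels numeric H x W x 3 array with intensities in `[0, 1]`.
#' @slot discMask binary H x W matrix (1 = optic disc), or a 0 x 0 matrix for
#'   unlabeled images.
#' @slot cupMask binary H x W matrix (1 = optic cup), or a 0 x 0 matrix.
#' @slot id character identifier.
#' @slot params list of generator parameters (empty for non-synthetic images).
#'
#' @examples
#' img <- makeSample(sceneParams(seed = 1))
#' img
#' @export
setClass("FundusImage",
  representation(pixels = "array", discMask = "matrix", cupMask = "matrix",
                 id = "character", params = "list"),
  prototype(discMask = matrix(0, 0, 0), cupMask = matrix(0, 0, 0),
            id = "sample", params = list()))

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (min(object@pixels) < 0 || max(object@pixels) > 1)
    return("pixel intensities must lie in [0, 1]")
  labeled <- length(object@discMask) > 0L
  if (labeled) {
    if (!identical(dim(object@discMask), d[1:2]) ||
        !identical(dim(object@cupMask), d[1:2]))
      return("masks must have the same spatial size as pixels")
    if (!all(object@discMask %in% c(0, 1)) || !all(object@cupMask %in% c(0, 1)))
      return("masks must be binary")
    if (any(object@cupMask > object@discMask))
      return("cup mask must be contained in the disc mask")
  }
  TRUE
})

#' MaskPair: disc and cup probability maps
#'
#' Per-pixel disc and cup probabilities produced by the segmentation decoder,
#' with the raw logits retained.
#'
#' @slot pDisc,pCup numeric H x W matrices with values in `[0, 1]`.
#' @slot logits list with elements `disc` and `cup` (H x W logit matrices).
#' @export
setClass("MaskPair",
  representation(pDisc = "matrix", pCup = "matrix", logits = "list"),
  prototype(logits = list()))

setValidity("MaskPair", function(object) {
  if (!identical(dim(object@pDisc), dim(object@pCup)))
    return("pDisc and pCup must have identical dimensions")
  if (min(object@pDisc) < 0 || max(object@pDisc) > 1 ||
      min(object@pCup) < 0 || max(object@pCup) > 1)
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' TokenTensor: flattened patch-token sequence
#'
#' A feature map folded into a token sequence with channels as rows. Position
#' `p` (0-based) of a map group `n` at pixel `(r, c)` is `n*h*w + r*w + c`, so
#' the number of positions is `P = N*h*w`.
#'
#' @slot values numeric C x P matrix of token features (channels x positions).
#' @slot gridShape integer vector `(h, w)`, the spatial origin of positions.
#' @slot groupSize integer N, number of feature-map groups in the sequence.
#' @export
setClass("TokenTensor",
  representation(values = "matrix", gridShape = "integer",
                 groupSize = "integer"),
  prototype(groupSize = 1L))

setValidity("TokenTensor", function(object) {
  if (length(object@gridShape) != 2L)
    return("gridShape must be (h, w)")
  P <- object@groupSize * prod(object@gridShape)
  if (ncol(object@values) != P)
    return(sprintf("P (%d) must equal N*h*w (%d)", ncol(object@values), P))
  TRUE
})

#' @describeIn FundusImage pixel array accessor
#' @param object,x a `FundusImage`
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
setMethod("imagePixels", "FundusImage", function(object) object@pixels)

#' @describeIn FundusImage disc ground-truth mask accessor
#' @export
setGeneric("discMask", function(object) standardGeneric("discMask"))
setMethod("discMask", "FundusImage", function(object) object@discMask)

#' @describeIn FundusImage cup ground-truth mask accessor
#' @export
setGeneric("cupMask", function(object) standardGeneric("cupMask"))
setMethod("cupMask", "FundusImage", function(object) object@cupMask)

#' @describeIn FundusImage identifier accessor
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
setMethod("sampleId", "FundusImage", function(object) object@id)

#' @describeIn FundusImage whether ground-truth masks are attached
#' @export
setGeneric("isLabeled", function(object) standardGeneric("isLabeled"))
setMethod("isLabeled", "FundusImage", function(object) length(object@discMask) > 0L)

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s': %d x %d RGB, %s\n", object@id, d[1], d[2],
              if (isLabeled(object))
                sprintf("labeled (disc %d px, cup %d px)",
                        sum(object@discMask), sum(object@cupMask))
              else "unlabeled"))
})

#' @describeIn MaskPair disc probability map accessor
#' @param object a `MaskPair`
#' @export
setGeneric("discProb", function(object) standardGeneric("discProb"))
setMethod("discProb", "MaskPair", function(object) object@pDisc)

#' @describeIn MaskPair cup probability map accessor
#' @export
setGeneric("cupProb", function(object) standardGeneric("cupProb"))
setMethod("cupProb", "MaskPair", function(object) object@pCup)

setMethod("show", "MaskPair", function(object) {
  d <- dim(object@pDisc)
  cat(sprintf("MaskPair: %d x %d probability maps (disc mean %.3f, cup mean %.3f)\n",
              d[1], d[2], mean(object@pDisc), mean(object@pCup)))
})

#' @describeIn TokenTensor token value matrix accessor
#' @param object a `TokenTensor`
#' @export
setGeneric("tokenValues", function(object) standardGeneric("tokenValues"))
setMethod("tokenValues", "TokenTensor", function(object) object@values)

setMethod("show", "TokenTensor", function(object) {
  cat(sprintf("TokenTensor: C=%d, P=%d (N=%d, grid %dx%d)\n",
              nrow(object@values), ncol(object@values), object@groupSize,
              object@gridShape[1], object@gridShape[2]))
})

# seed-scoped evaluation preserving the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
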