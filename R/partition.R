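# Personalized/shared parameter partition.
#
# Federated strategies differ in which tensors stay on the client
# (personalized, W_H) and which are sent to the server (shared, W_R). The
# partition is expressed per parameter *role*, so it applies to any
# architecture built by build_unet().

.partition_roles <- c("conv_weight", "conv_bias", "bn_gamma", "bn_beta",
                      "bn_running_mean", "bn_running_var",
                      "head_weight", "head_bias")

#' Partition presets: which parameter roles are personalized
#'
#' Returns the assignment \code{role -> personalized/shared} for a named
#' preset:
#' \describe{
#'   \item{paf_fed}{segmentation head and BN running statistics personalized;
#'     BN affine (gamma, beta) and all convolutions shared. The frequency
#'     aggregation strategies use this partition.}
#'   \item{fedavg}{everything shared (classic federated averaging).}
#'   \item{fedbn}{all four BN roles personalized.}
#'   \item{silobn}{only the BN running statistics personalized.}
#'   \item{fedrep}{only the segmentation head personalized.}
#'   \item{local}{everything personalized (no communication).}
#' }
#'
#' @param preset preset name; omit to get the list of valid names.
#' @return named character vector over all roles, values
#'   \code{"personalized"} or \code{"shared"}; or the preset names.
#' @export
partition_presets <- function(preset = NULL) {
  personalized <- list(
    paf_fed = c("head_weight", "head_bias",
                "bn_running_mean", "bn_running_var"),
    fedavg  = character(0),
    fedbn   = c("bn_gamma", "bn_beta", "bn_running_mean", "bn_running_var"),
    silobn  = c("bn_running_mean", "bn_running_var"),
    fedrep  = c("head_weight", "head_bias"),
    local   = .partition_roles
  )
  if (is.null(preset)) return(names(personalized))
  if (!preset %in% names(personalized)) {
    stop("unknown partition preset '", preset, "'; valid presets: ",
         paste(names(personalized), collapse = ", "))
  }
  assignment <- ifelse(.partition_roles %in% personalized[[preset]],
                       "personalized", "shared")
  names(assignment) <- .partition_roles
  assignment
}

#' Classify a model's parameters as personalized or shared
#'
#' Applies a partition preset to every named tensor of the model, using its
#' role.
#'
#' @param model a \code{freqfed_unet}.
#' @param preset one of \code{partition_presets()}.
#' @return object of class \code{partition_spec}: list with \code{preset},
#'   \code{assignment} (role map) and \code{param_class} (named vector over
#'   tensor names).
#' @export
classify_parameters <- function(model, preset) {
  assignment <- partition_presets(preset)
  param_class <- assignment[model$roles]
  names(param_class) <- names(model$roles)
  structure(list(preset = preset, assignment = assignment,
                 param_class = param_class),
            class = "partition_spec")
}

#' Split a parameter set into personalized and shared maps
#'
#' @param model a \code{freqfed_unet} (or a named parameter list together
#'   with a spec covering all its names).
#' @param spec a \code{partition_spec} from \code{\link{classify_parameters}}.
#' @return list with named-tensor maps \code{W_H} (personalized) and
#'   \code{W_R} (shared); their union is the full parameter set, their
#'   intersection empty.
#' @export
split_weights <- function(model, spec) {
  params <- if (inherits(model, "freqfed_unet")) model$params else model
  cls <- spec$param_class
  if (!all(names(params) %in% names(cls))) {
    stop("partition spec does not cover parameter(s): ",
         paste(setdiff(names(params), names(cls)), collapse = ", "))
  }
  cls <- cls[names(params)]
  list(W_H = params[cls == "personalized"],
       W_R = params[cls == "shared"])
}

#' Merge personalized and shared maps back into one parameter set
#'
#' @param W_H named-tensor map of personalized parameters.
#' @param W_R named-tensor map of shared parameters.
#' @return the combined named list; errors if any name appears in both maps
#'   or twice in one.
#' @export
merge_weights <- function(W_H, W_R) {
  nm <- c(names(W_H), names(W_R))
  if (anyDuplicated(nm)) {
    stop("duplicate parameter name(s) in merge: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  c(W_H, W_R)
}
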