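#' Define a single DCE attribute
#'
#' An attribute is a characteristic of the alternatives in a discrete choice
#' experiment (e.g. the capitation rate per individual per year) together with
#' its possible levels. Each level carries a numeric utility code (months,
#' shillings, or an integer category code); under `coding = "linear"` the code
#' itself enters the utility function with a single coefficient, under
#' `coding = "indicator"` the attribute is dummy-expanded against its first
#' (reference) level.
#'
#' @param name short identifier, unique within an attribute set.
#' @param codes numeric level codes, strictly increasing; their range
#'   (max - min) is the lever used by relative-importance scores.
#' @param labels human-readable level labels, same length as `codes`, unique.
#' @param coding `"linear"` (one coefficient on the code) or `"indicator"`
#'   (one coefficient per non-reference level).
#' @param sign expected coefficient sign from prior knowledge:
#'   `"positive"`, `"negative"` or `"none"`.
#' @param prior point prior coefficient used for D-efficient design search.
#' @param cost logical; is this the monetary attribute used as the numeraire
#'   for willingness-to-accept?
#' @param label optional display name (defaults to `name`).
#' @return an object of class `dce_attribute`.
#' @export
dce_attribute <- function(name, codes, labels, coding = "linear",
                          sign = "none", prior = 0, cost = FALSE,
                          label = name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("attribute needs a non-empty name", call. = FALSE)
  codes <- as.numeric(codes)
  if (length(codes) < 2L)
    stop("attribute '", name, "': needs at least 2 levels", call. = FALSE)
  if (any(!is.finite(codes)) || any(diff(codes) <= 0))
    stop("attribute '", name, "': level codes must be finite and strictly increasing",
         call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != length(codes))
    stop("attribute '", name, "': labels and codes differ in length", call. = FALSE)
  if (anyDuplicated(labels))
    stop("attribute '", name, "': duplicate level labels", call. = FALSE)
  coding <- match.arg(coding, c("linear", "indicator"))
  sign <- match.arg(sign, c("positive", "negative", "none"))
  prior <- as.numeric(prior)
  stopifnot(length(prior) == 1L, is.finite(prior))
  structure(
    list(name = name, label = label, codes = codes, labels = labels,
         coding = coding, sign = sign, prior = prior, cost = isTRUE(cost)),
    class = "dce_attribute")
}

#' Assemble an attribute set
#'
#' The ordered collection of attributes that defines the utility
#' specification `U = X beta + eps`, optionally with an alternative-specific
#' constant (ASC) for an opt-out / no-choice alternative. The opt-out is
#' modelled as an all-zero attribute row plus the ASC.
#'
#' @param attributes list of [dce_attribute()] objects.
#' @param optout_asc include an ASC for the opt-out alternative?
#' @param optout_prior point prior for the ASC (design search only).
#' @param name identifier for the set (used in file headers).
#' @return an object of class `dce_attributes`.
#' @export
dce_attribute_set <- function(attributes, optout_asc = TRUE,
                              optout_prior = 0, name = "attribute_set") {
  if (!length(attributes) || !all(vapply(attributes, inherits, TRUE, "dce_attribute")))
    stop("'attributes' must be a non-empty list of dce_attribute objects",
         call. = FALSE)
  nms <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate attribute names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  ncost <- sum(vapply(attributes, `[[`, TRUE, "cost"))
  if (ncost > 1L)
    stop("at most one cost attribute allowed, found ", ncost, call. = FALSE)
  names(attributes) <- nms
  structure(
    list(name = name, attributes = attributes, optout_asc = isTRUE(optout_asc),
         optout_prior = as.numeric(optout_prior)),
    class = "dce_attributes")
}

#' @export
print.dce_attributes <- function(x, ...) {
  cat("DCE attribute set '", x$name, "': ", length(x$attributes),
      " attributes, K = ", n_params(x),
      if (x$optout_asc) " (incl. opt-out ASC)" else "", "\n", sep = "")
  for (a in x$attributes) {
    cat(sprintf("  %-14s %-9s sign=%-8s prior=% .4g%s  codes: %s\n",
                a$name, a$coding, a$sign, a$prior,
                if (a$cost) " [cost]" else "",
                paste(a$codes, collapse = ", ")))
  }
  invisible(x)
}

#' Number of utility parameters implied by an attribute set
#'
#' Linear attributes contribute one coefficient, indicator attributes one per
#' non-reference level, plus one for the opt-out ASC if present.
#' @param attrs a `dce_attributes` object.
#' @return integer K.
#' @export
n_params <- function(attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  k <- sum(vapply(attrs$attributes, function(a)
    if (a$coding == "linear") 1L else length(a$codes) - 1L, 1L))
  k + as.integer(attrs$optout_asc)
}

#' Names of the utility parameters, in encoding order
#' @param attrs a `dce_attributes` object.
#' @export
param_names <- function(attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  nm <- unlist(lapply(attrs$attributes, function(a) {
    if (a$coding == "linear") a$name
    else paste0(a$name, ".", seq_along(a$codes)[-1L])
  }), use.names = FALSE)
  if (attrs$optout_asc) nm <- c(nm, "optout")
  nm
}

#' Level-code range of each attribute
#'
#' `max(codes) - min(codes)`; multiplied by `|beta|` this gives the maximum
#' utility effect used by relative-importance scores.
#' @param attrs a `dce_attributes` object.
#' @return named numeric vector.
#' @export
attribute_ranges <- function(attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  vapply(attrs$attributes, function(a) max(a$codes) - min(a$codes), 0)
}

#' Encode one alternative as a utility row
#'
#' Builds the length-K numeric row of the design matrix for a single
#' alternative: level codes (linear coding) or dummies (indicator coding) in
#' attribute order, then the opt-out ASC slot. Opt-out rows are all-zero with
#' a 1 in the ASC slot.
#'
#' @param attrs a `dce_attributes` object.
#' @param assignment named vector/list of 1-based level indices, one per
#'   attribute (ignored for opt-out rows).
#' @param is_optout is this the opt-out alternative?
#' @return named numeric vector of length `n_params(attrs)`.
#' @export
encode_alternative <- function(attrs, assignment = NULL, is_optout = FALSE) {
  stopifnot(inherits(attrs, "dce_attributes"))
  pn <- param_names(attrs)
  row <- stats::setNames(numeric(length(pn)), pn)
  if (is_optout) {
    if (!attrs$optout_asc)
      stop("attribute set has no opt-out ASC", call. = FALSE)
    row["optout"] <- 1
    return(row)
  }
  if (is.null(assignment))
    stop("assignment required for a non-opt-out alternative", call. = FALSE)
  assignment <- unlist(assignment)
  unknown <- setdiff(names(assignment), names(attrs$attributes))
  if (length(unknown))
    stop("unknown attribute in assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(names(attrs$attributes), names(assignment))
  if (length(missing))
    stop("assignment missing attribute: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (a in attrs$attributes) {
    i <- as.integer(assignment[[a$name]])
    if (is.na(i) || i < 1L || i > length(a$codes))
      stop("attribute '", a$name, "': level index ", assignment[[a$name]],
           " out of range 1..", length(a$codes), call. = FALSE)
    if (a$coding == "linear") {
      row[a$name] <- a$codes[i]
    } else if (i > 1L) {
      row[paste0(a$name, ".", i)] <- 1
    }
  }
  row
}

#' Prior coefficient vector of an attribute set
#'
#' Point priors in parameter order for design optimization. Indicator
#' attributes spread the stated prior linearly over the code spacing so that
#' the implied utility ordering matches the linear prior.
#' @param attrs a `dce_attributes` object.
#' @return named numeric vector of length K.
#' @export
prior_vector <- function(attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  pr <- unlist(lapply(attrs$attributes, function(a) {
    if (a$coding == "linear") stats::setNames(a$prior, a$name)
    else stats::setNames(a$prior * (a$codes[-1L] - a$codes[1L]),
                         paste0(a$name, ".", seq_along(a$codes)[-1L]))
  }))
  if (attrs$optout_asc) pr <- c(pr, optout = attrs$optout_prior)
  pr
}

#' Read an attribute configuration file
#'
#' The configuration is Debian-control-style structured text (one blank-line
#' separated block per attribute, preceded by a header block), the format
#' produced by `write.dcf`. Header fields: `config` (set name), `optout_asc`
#' (yes/no), `optout_prior`. Attribute fields: `attribute`, `label`, `codes`
#' (space-separated numbers), `levels` (labels separated by `;`), `coding`,
#' `sign`, `prior`, `cost` (yes/no). Two fixtures ship with the package:
#' `system.file("extdata", "pilot_table9.dcf", package = "capdce")` (the
#' five-attribute pilot set) and `"final_table12.dcf"` (the four-attribute
#' final set).
#'
#' @param path file path.
#' @return a validated `dce_attributes` object.
#' @export
read_attribute_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  blocks <- read.dcf(path, all = FALSE)
  if (!nrow(blocks)) stop("empty attribute config: ", path, call. = FALSE)
  fld <- function(i, what, default = NULL) {
    v <- if (what %in% colnames(blocks)) blocks[i, what] else NA
    if (is.na(v)) {
      if (is.null(default))
        stop("config block ", i, ": missing field '", what, "'", call. = FALSE)
      default
    } else v
  }
  yesno <- function(x) tolower(trimws(x)) %in% c("yes", "true", "1")
  hdr <- 1L
  if (!("config" %in% colnames(blocks)) || is.na(blocks[1L, "config"]))
    stop("first block must be a header with a 'config' field", call. = FALSE)
  specs <- lapply(seq_len(nrow(blocks))[-hdr], function(i) {
    dce_attribute(
      name   = fld(i, "attribute"),
      codes  = scan(text = fld(i, "codes"), quiet = TRUE),
      labels = trimws(strsplit(fld(i, "levels"), ";", fixed = TRUE)[[1L]]),
      coding = fld(i, "coding", "linear"),
      sign   = fld(i, "sign", "none"),
      prior  = as.numeric(fld(i, "prior", "0")),
      cost   = yesno(fld(i, "cost", "no")),
      label  = fld(i, "label", fld(i, "attribute")))
  })
  dce_attribute_set(
    specs,
    optout_asc   = yesno(fld(hdr, "optout_asc", "yes")),
    optout_prior = as.numeric(fld(hdr, "optout_prior", "0")),
    name         = fld(hdr, "config"))
}
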