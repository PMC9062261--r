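#' The default cardiomyocyte metabolism model
#'
#' Returns the complete model as tabulated: five compartments, the full
#' species registry with initial values and dynamics kinds, and every kinetic,
#' thermodynamic and physical parameter.  The model ships as a structured YAML
#' document under \code{inst/extdata/} and is schema-validated on load; the
#' in-memory object round-trips losslessly through [writeModel()]/[readModel()].
#'
#' @return A [CardioModel-class] object.
#' @examples
#' mod <- defaultModel()
#' initialState(mod)[c("ATP_c", "CrP_c", "O2_v")]
#' @export
defaultModel <- function() {
  path <- system.file("extdata", "default_model.yaml", package = "cardiomyosim")
  if (nzchar(path)) readModel(path) else .modelFromRegistry()
}

.modelFromRegistry <- function() {
  new("CardioModel",
      compartments = .compartmentTable(),
      species      = .speciesTable(),
      parameters   = .defaultParams())
}

#' @describeIn defaultModel Named override preset selecting the alternative
#'   printed Mg-ATP dissociation constant (2.45e-5 mM, from the ATP-synthase
#'   parameter table) instead of the transporter-table default 0.024 mM.
#' @export
kMgATPF1TablePreset <- function() {
  list(parameterOverride("MgB.KMgATP", 2.45e-5))
}

# ---- accessors -------------------------------------------------------------

#' Model accessors
#'
#' @param model A [CardioModel-class].
#' @return \code{compartmentTable}: data.frame of compartment volumes;
#'   \code{speciesTable}: the species registry; \code{kineticParameters}: the
#'   nested parameter list; \code{initialState}: named numeric vector of all
#'   initial values (mM; dPsi in mV).
#' @export
compartmentTable <- function(model) model@compartments

#' @rdname compartmentTable
#' @export
speciesTable <- function(model) model@species

#' @rdname compartmentTable
#' @export
kineticParameters <- function(model) model@parameters

#' @rdname compartmentTable
#' @export
initialState <- function(model) {
  stats::setNames(model@species$initial, model@species$name)
}

# ---- overrides -------------------------------------------------------------

#' Parameter and initial-value overrides
#'
#' An override addresses one entry of the model by dotted path: either a
#' kinetic parameter (\code{"HK.Vf"}, \code{"phys.CIM"}) or an initial value
#' (\code{"initial.O2_v"}).  Multiplicative overrides scale the current value.
#'
#' @param path dotted path into the parameter set, or \code{"initial.<species>"}.
#' @param value replacement value (or factor when \code{multiplicative}).
#' @param multiplicative scale instead of replace.
#' @return A \code{parameterOverride} list object.
#' @examples
#' m <- applyOverrides(defaultModel(), list(parameterOverride("HK.Vf", 1.01, TRUE)))
#' kineticParameters(m)$HK$Vf
#' @export
parameterOverride <- function(path, value, multiplicative = FALSE) {
  stopifnot(is.character(path), length(path) == 1L,
            is.numeric(value), length(value) == 1L)
  structure(list(path = path, value = value, multiplicative = multiplicative),
            class = "parameterOverride")
}

#' Apply overrides to a model
#'
#' Returns a new model with the overrides applied; the base model is not
#' modified and an empty override list is the identity.
#'
#' @param model A [CardioModel-class].
#' @param overrides list of [parameterOverride()] objects.
#' @return A new [CardioModel-class].
#' @export
applyOverrides <- function(model, overrides = list()) {
  stopifnot(is(model, "CardioModel"), is.list(overrides))
  for (ov in overrides) {
    if (!inherits(ov, "parameterOverride"))
      stop("overrides must be created with parameterOverride()")
    parts <- strsplit(ov$path, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("cannot resolve override path: ", ov$path)
    if (parts[1] == "initial") {
      i <- match(parts[2], model@species$name)
      if (is.na(i)) stop("cannot resolve override path: ", ov$path)
      cur <- model@species$initial[i]
      model@species$initial[i] <-
        if (ov$multiplicative) cur * ov$value else ov$value
    } else {
      blk <- model@parameters[[parts[1]]]
      if (is.null(blk) || is.null(blk[[parts[2]]]))
        stop("cannot resolve override path: ", ov$path)
      cur <- blk[[parts[2]]]
      model@parameters[[parts[1]]][[parts[2]]] <-
        if (ov$multiplicative) cur * ov$value else ov$value
    }
  }
  validObject(model)
  model
}

# internal: scale one enzyme's activity parameters by `factor`
.scaleActivity <- function(model, enzyme, factor) {
  amap <- .activityMap()
  if (is.null(amap[[enzyme]])) stop("unknown enzyme/reaction: ", enzyme)
  applyOverrides(model, lapply(amap[[enzyme]]$pars, parameterOverride,
                               value = factor, multiplicative = TRUE))
}

# ---- serialization ---------------------------------------------------------

.fmtNum <- function(x) {
  # shortest decimal representation that round-trips a double exactly
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g")
}

#' Read and write the model as a structured YAML document
#'
#' The writer emits a deterministic document (fixed ordering, shortest exact
#' numeric representations), so serialize -> deserialize -> serialize is
#' byte-identical.  The reader validates the document structure (compartment
#' set, species registry order and kinds, parameter completeness).
#'
#' @param model A [CardioModel-class].
#' @param path file path.
#' @return \code{readModel}: a [CardioModel-class]; \code{writeModel}: the
#'   path, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "CardioModel"))
  ln <- c("# cardiomyosim model definition", "compartments:")
  cmp <- model@compartments
  for (i in seq_len(nrow(cmp)))
    ln <- c(ln, sprintf("  %s: %s", cmp$name[i], .fmtNum(cmp$volume[i])))
  ln <- c(ln, "species:")
  sp <- model@species
  for (i in seq_len(nrow(sp)))
    ln <- c(ln, sprintf("  - {name: %s, compartment: %s, unit: %s, initial: %s, kind: %s}",
                        sp$name[i], sp$compartment[i], sp$unit[i],
                        .fmtNum(sp$initial[i]), sp$kind[i]))
  ln <- c(ln, "parameters:")
  par <- model@parameters
  for (blk in names(par)) {
    ln <- c(ln, sprintf("  %s:", blk))
    for (nm in names(par[[blk]]))
      ln <- c(ln, sprintf("    %s: %s", nm, .fmtNum(par[[blk]][[nm]])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- yaml::read_yaml(path)
  need <- c("compartments", "species", "parameters")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model document is missing section(s): ", paste(miss, collapse = ", "))
  cmp <- data.frame(name = names(doc$compartments),
                    volume = as.numeric(unlist(doc$compartments)),
                    stringsAsFactors = FALSE)
  sp <- do.call(rbind, lapply(doc$species, function(s) {
    need <- c("name", "compartment", "unit", "initial", "kind")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("species entry missing field(s): ", paste(miss, collapse = ", "))
    data.frame(name = s$name, compartment = s$compartment, unit = s$unit,
               initial = as.numeric(s$initial), kind = s$kind,
               stringsAsFactors = FALSE)
  }))
  model <- new("CardioModel", compartments = cmp, species = sp,
               parameters = lapply(doc$parameters, function(b) lapply(b, as.numeric)))
  validObject(model)
  model
}
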