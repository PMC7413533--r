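#' Secondary-structure region configuration
#'
#' Declares, per homodimer, the chain identifiers, the residue ranges of the
#' secondary-structure elements (six helices, two strands and the inter-domain
#' loop of a winged helix-turn-helix regulator), the DNA-binding-domain range
#' (start of the second helix through the end of the second strand), the probe
#' residue whose C-alpha pair across the two protein chains defines the
#' inter-recognition-helix distance, and the simulation temperature. Ranges use
#' author residue numbering, 1-based and inclusive, identical on both chains of
#' the symmetric dimer.
#'
#' @param chains character vector of the two protein chain identifiers, in
#'   order; the primed-residue convention (e.g. K70') refers to the second.
#' @param elements named list of `c(lo, hi)` residue ranges (names such as
#'   `alpha1` ... `alpha6`, `beta1`, `beta2`, `loop1`). May be empty if only
#'   the domain range is needed.
#' @param dna_binding_domain `c(lo, hi)` residue range of the DNA-binding
#'   domain; defaults to spanning `alpha2` through `beta2` when both are given.
#' @param probe_residue residue number carrying the probe C-alpha on each
#'   chain (default 71).
#' @param temperature simulation temperature, K (default 300).
#' @return object of class `region_config`.
#' @export
region_config <- function(chains = c("A", "B"), elements = list(),
                          dna_binding_domain = NULL, probe_residue = 71,
                          temperature = 300) {
  if (length(chains) != 2L) stop("exactly two protein chains required")
  elements <- lapply(elements, function(r) as.integer(r[1:2]))
  if (is.null(dna_binding_domain)) {
    if (all(c("alpha2", "beta2") %in% names(elements)))
      dna_binding_domain <- c(elements$alpha2[1L], elements$beta2[2L])
    else stop("dna_binding_domain not given and alpha2/beta2 ranges absent")
  }
  dna_binding_domain <- as.integer(dna_binding_domain[1:2])
  if (dna_binding_domain[1L] > dna_binding_domain[2L])
    stop("dna_binding_domain range reversed")
  helix_like <- grepl("^(alpha|beta)", names(elements))
  if (sum(helix_like) > 1L) {
    rng <- elements[helix_like]
    ord <- order(vapply(rng, `[`, integer(1L), 1L))
    rng <- rng[ord]
    for (k in seq_len(length(rng) - 1L))
      if (rng[[k + 1L]][1L] <= rng[[k]][2L])
        stop("overlapping secondary-structure ranges: ",
             names(rng)[k], " and ", names(rng)[k + 1L])
  }
  out <- list(chains = chains, elements = elements,
              dna_binding_domain = dna_binding_domain,
              probe_residue = as.integer(probe_residue),
              temperature = as.numeric(temperature))
  class(out) <- "region_config"
  out
}

#' Read a region configuration from YAML or JSON
#'
#' The file maps directly onto the arguments of [region_config()]; see
#' `inst/extdata/zitr_regions.yaml` for a worked example (chains A/B, probe
#' residue 71).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `region_config`.
#' @export
read_region_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  region_config(chains = unlist(cfg$chains),
                elements = lapply(cfg$elements, unlist),
                dna_binding_domain = unlist(cfg$dna_binding_domain),
                probe_residue = if (is.null(cfg$probe_residue)) 71 else cfg$probe_residue,
                temperature = if (is.null(cfg$temperature)) 300 else cfg$temperature)
}

#' Write a region configuration to YAML
#' @param region a `region_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_config <- function(region, path) {
  yaml::write_yaml(unclass(region), path)
  invisible(path)
}
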