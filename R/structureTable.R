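## Structure lookup table: code -> (name, density, SUV).

## Structure codes used by the default anatomy model
.CODES <- c(air = 0L, soft_tissue = 1L, lungs = 2L, liver = 3L, spleen = 4L,
            kidneys = 5L, pancreas = 6L, stomach_wall = 7L,
            bladder_contents = 8L, tumours = 9L)

## Rest-of-body SUVs are free calibration constants: they are not reported
## for structures with SUV below 5 and are chosen once so that the imaged
## mid-thigh-to-forehead portion of a default cohort phantom holds ~40% of
## the injected activity (see the methods vignette). Do not retune.
.SOFT_TISSUE_SUV <- 0.047
.LUNG_SUV <- 0.10

#' Default structure lookup table
#'
#' The structures with SUV above 5 carry the published
#' \[68Ga\]Ga-DOTA-TOC densities and SUVs (bladder contents 1.00/12.0,
#' kidneys 1.05/9.7, liver 1.06/9.5, pancreas 1.04/5.5, spleen 1.06/23.2,
#' stomach wall 1.05/7.0, tumours 1.05/22.9).  Generic soft tissue and
#' lungs carry low calibration SUVs chosen so the imaged portion of a
#' default phantom holds about 40\% of the injected activity.
#'
#' @return a [StructureTable-class].
#' @export
#' @examples
#' defaultStructureTable()
defaultStructureTable <- function() {
  tb <- data.frame(
    code = unname(.CODES),
    name = names(.CODES),
    density_g_cm3 = c(0, 1.00, 0.30, 1.06, 1.06, 1.05, 1.04, 1.05, 1.00, 1.05),
    suv = c(0, .SOFT_TISSUE_SUV, .LUNG_SUV, 9.5, 23.2, 9.7, 5.5, 7.0, 12.0,
            22.9),
    stringsAsFactors = FALSE
  )
  methods::new("StructureTable", table = tb)
}

#' Read / write a structure table as CSV
#'
#' The CSV carries the header `code,name,density_g_cm3,suv`.
#'
#' @param path file path.
#' @param x a [StructureTable-class].
#' @return `readStructureTable` returns a [StructureTable-class];
#'   `writeStructureTable` returns `path` invisibly.
#' @export
readStructureTable <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  tb$code <- as.integer(tb$code)
  methods::new("StructureTable", table = tb)
}

#' @rdname readStructureTable
#' @export
writeStructureTable <- function(x, path) {
  stopifnot(methods::is(x, "StructureTable"))
  utils::write.csv(x@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structure table accessors
#'
#' Resolve integer codes to densities or SUVs.  Unknown codes raise an
#' error naming the offending code.
#'
#' @param table a [StructureTable-class].
#' @param codes integer vector or array of structure codes.
#' @return numeric of the same shape as `codes`.
#' @export
structureDensity <- function(table, codes) {
  .lookupColumn(table, codes, "density_g_cm3")
}

#' @rdname structureDensity
#' @export
structureSuv <- function(table, codes) {
  .lookupColumn(table, codes, "suv")
}

.lookupColumn <- function(table, codes, column) {
  stopifnot(methods::is(table, "StructureTable"))
  tb <- table@table
  d <- dim(codes)
  iv <- as.integer(codes)
  pos <- match(iv, tb$code)
  if (anyNA(pos)) {
    bad <- sort(unique(iv[is.na(pos)]))
    stop(sprintf("structure code(s) not in table: %s",
                 paste(bad, collapse = ", ")))
  }
  out <- tb[[column]][pos]
  if (!is.null(d)) dim(out) <- d
  out
}

#' Code of a named structure
#'
#' @param name structure name as it appears in the table
#'   (e.g. `"liver"`).
#' @param table a [StructureTable-class].
#' @return the integer code.
#' @export
structureCode <- function(name, table = defaultStructureTable()) {
  tb <- table@table
  pos <- match(name, tb$name)
  if (is.na(pos)) stop(sprintf("no structure named '%s' in table", name))
  tb$code[pos]
}

## Per-voxel density honouring the phantom's forced-weight density scale
## (applied to the generic soft-tissue code only)
phantomDensity <- function(phantom, table) {
  dens <- structureDensity(table, phantom@codes)
  if (phantom@densityScale != 1) {
    sel <- phantom@codes == phantom@softTissueCode
    dens[sel] <- dens[sel] * phantom@densityScale
  }
  dens
}
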