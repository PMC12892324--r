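# Bridge to the RDKit helper script (inst/python/chem_helper.py).
#
# All chemistry primitives (SMILES parsing, canonicalization, Morgan
# fingerprints, Crippen logP, SDF reading) are delegated to RDKit through a
# batched subprocess with CSV hand-off; everything downstream is pure R.

the_chem <- new.env(parent = emptyenv())

chem_python <- function() {
  p <- Sys.getenv("VOTEDOCK_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    vd_stop(paste("no 'python' interpreter on PATH; the standardization and",
                  "fingerprint functions need Python with RDKit"))
  }
  p
}

chem_helper_path <- function() {
  path <- system.file("python", "chem_helper.py", package = "votedock")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet installed
    path <- file.path("inst", "python", "chem_helper.py")
  }
  if (!file.exists(path)) vd_stop("chem_helper.py not found")
  normalizePath(path)
}

#' Is the RDKit chemistry backend available?
#'
#' @return `TRUE` if `python` with RDKit can be invoked.
#' @export
chem_backend_available <- function() {
  if (!is.null(the_chem$available)) return(the_chem$available)
  ok <- tryCatch({
    py <- chem_python()
    status <- suppressWarnings(
      system2(py, c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE))
    identical(status, 0L)
  }, error = function(e) FALSE)
  the_chem$available <- ok
  ok
}

# Run one helper subcommand on a data.frame (must have the columns the
# subcommand expects, usually id + smiles); returns the output data.frame.
chem_tool <- function(command, df, args = character(), input_path = NULL) {
  py <- chem_python()
  inp <- input_path %||% tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(if (is.null(input_path)) inp, out)), add = TRUE)
  if (is.null(input_path)) {
    utils::write.csv(df, inp, row.names = FALSE)
  }
  err <- tempfile()
  status <- system2(py, c(chem_helper_path(), command, inp, out,
                          as.character(args)),
                    stdout = FALSE, stderr = err)
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    vd_stop("chemistry backend '%s' failed (exit %s): %s", command,
            status, msg)
  }
  read.csv(out, stringsAsFactors = FALSE,
           colClasses = if (command == "fingerprint") {
             c(id = "character", bits = "character")
           } else NA)
}
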