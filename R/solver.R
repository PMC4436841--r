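# Thin interface to a MILP backend.  The 0-1 assignment models are solved
# with the HiGHS solver through scipy.optimize.milp, driven by the bundled
# helper inst/python/solve_milp.py in a single batched subprocess call.
# HiGHS is deterministic for a fixed model, so schedules are reproducible.

find_python <- function() {
  opt <- getOption("theatreplan.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(path)
  }
  abort(paste0(
    "no `python` interpreter found on PATH: the MILP backend runs HiGHS via ",
    "scipy.optimize.milp; set options(theatreplan.python = \"/path/to/python\")"
  ))
}

milp_helper_path <- function() {
  path <- system.file("python", "solve_milp.py", package = "theatreplan")
  if (!nzchar(path)) abort("bundled solver helper solve_milp.py not found")
  path
}

# problems: list of lists with fields n, obj, aub/bub, aeq/beq,
# mip_rel_gap, time_limit (1-based triplet indices).  Returns the parsed
# list of results.
milp_solve_batch <- function(problems) {
  if (length(problems) == 0) return(list())
  wrap <- function(p) {
    p$obj <- I(p$obj)
    p$bub <- I(p$bub %||% numeric(0))
    p$beq <- I(p$beq %||% numeric(0))
    p$aub <- lapply(p$aub %||% list(i = integer(0), j = integer(0),
                                    v = numeric(0)), I)
    p$aeq <- lapply(p$aeq %||% list(i = integer(0), j = integer(0),
                                    v = numeric(0)), I)
    p
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(lapply(unname(problems), wrap), infile,
                       auto_unbox = TRUE, digits = NA, na = "null")
  status <- system2(find_python(), c(milp_helper_path(), infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(outfile)) {
    abort(paste0("MILP backend failed (exit ", code, "):\n",
                 paste(status, collapse = "\n")))
  }
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}
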