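#!/usr/bin/env Rscript
# Download the deposited genome records used by the sequence-level acceptance
# checks into inst/extdata/ (NETWORK REQUIRED; the package itself never
# fetches anything).
#
# Usage: Rscript scripts/fetch_accessions.R [destdir]

dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else "inst/extdata"
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

fetch <- function(acc, rettype = "gbwithparts", ext = ".gb") {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", acc, "&rettype=", rettype, "&retmode=text")
  path <- file.path(dest, paste0(acc, ext))
  message("fetching ", acc, " -> ", path)
  utils::download.file(url, path, quiet = TRUE)
  Sys.sleep(0.5)  # NCBI rate limit
  path
}

# 45 kb halovirus genome (sequence-level characterization checks)
fetch("MT152698")
# 11.8 kb pleolipoprovirus circular form and the host draft contig carrying
# its integration site (att-core check against the tRNA-Pro 3' end)
fetch("MW344764")
fetch("AOJL01000020")
message("done")
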