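# Amino-acid code tables (loaded first; other files use them at load time).

AA_THREE <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")

three_to_one <- function(res) {
  out <- AA_ONE[match(res, AA_THREE)]
  out[is.na(out)] <- "X"
  out
}

one_to_three <- function(aa) {
  out <- AA_THREE[match(aa, AA_ONE)]
  if (anyNA(out))
    stop_parse(paste0("unknown one-letter amino acid code: ",
                      paste(aa[is.na(out)], collapse = ", ")))
  out
}
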