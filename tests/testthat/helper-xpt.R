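# Minimal SAS transport (XPT v5) writer used to craft binary fixtures at
# test time. Numeric values are encoded as IBM System/370 doubles,
# character values as fixed-width ASCII. foreign::read.xport serves as the
# independent decoder of these hand-built bytes.

xpt_pad <- function(s, width) {
  s <- substr(s, 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

xpt_header_record <- function(kind, middle = strrep("0", 30)) {
  paste0("HEADER RECORD*******", xpt_pad(kind, 8),
         "HEADER RECORD!!!!!!!", middle, "  ")
}

ieee_to_ibm <- function(x) {
  if (is.na(x)) return(as.raw(c(0x2e, rep(0x00, 7)))) # SAS missing '.'
  if (x == 0) return(raw(8))
  sign_bit <- if (x < 0) 0x80 else 0x00
  x <- abs(x)
  e <- ceiling(log(x, 16))
  f <- x / 16^e
  while (f >= 1) { e <- e + 1; f <- x / 16^e }
  while (f < 1 / 16) { e <- e - 1; f <- x / 16^e }
  frac <- round(f * 2^56)
  bytes <- raw(8)
  bytes[1] <- as.raw(bitwOr(sign_bit, e + 64))
  for (i in 8:2) {
    bytes[i] <- as.raw(frac %% 256)
    frac <- frac %/% 256
  }
  bytes
}

xpt_short <- function(v) as.raw(c(v %/% 256, v %% 256))
xpt_long <- function(v) {
  as.raw(c(v %/% 16777216, (v %/% 65536) %% 256, (v %/% 256) %% 256, v %% 256))
}

xpt_namestr <- function(varnum, name, is_char, length, pos) {
  c(xpt_short(if (is_char) 2 else 1), # ntype
    xpt_short(0),                     # nhfun
    xpt_short(length),                # nlng
    xpt_short(varnum),                # nvar0
    charToRaw(xpt_pad(name, 8)),
    charToRaw(strrep(" ", 40)),       # nlabel
    charToRaw(strrep(" ", 8)),        # nform
    xpt_short(0), xpt_short(0), xpt_short(0), # nfl, nfd, nfj
    charToRaw("  "),                  # nfill
    charToRaw(strrep(" ", 8)),        # niform
    xpt_short(0), xpt_short(0),       # nifl, nifd
    xpt_long(pos),
    charToRaw(strrep(" ", 52)))
}

# write a data.frame (numeric and character columns) as a v5 transport file
write_xpt <- function(df, path, dsname = "COHORT") {
  stamp <- "01JAN26:00:00:00"
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x) writeBin(x, con)
  puts <- function(s) put(charToRaw(s))

  puts(xpt_header_record("LIBRARY "))
  puts(paste0(xpt_pad("SAS", 8), xpt_pad("SAS", 8), xpt_pad("SASLIB", 8),
              xpt_pad("9.4", 8), xpt_pad("R", 8), strrep(" ", 24), stamp))
  puts(paste0(stamp, strrep(" ", 64)))
  puts(xpt_header_record("MEMBER  ",
                         paste0(strrep("0", 16), "01600000000140")))
  puts(xpt_header_record("DSCRPTR "))
  puts(paste0(xpt_pad("SAS", 8), xpt_pad(dsname, 8), xpt_pad("SASDATA", 8),
              xpt_pad("9.4", 8), xpt_pad("R", 8), strrep(" ", 24), stamp))
  puts(paste0(stamp, strrep(" ", 16), strrep(" ", 40), xpt_pad("", 8)))
  puts(xpt_header_record("NAMESTR ",
                         paste0(strrep("0", 6), sprintf("%04d", ncol(df)),
                                strrep("0", 20))))

  is_char <- vapply(df, is.character, logical(1))
  widths <- ifelse(is_char,
                   pmax(1, vapply(df, function(v) max(nchar(v)), numeric(1))),
                   8)
  pos <- cumsum(c(0, widths[-length(widths)]))
  ns <- unlist(lapply(seq_along(df), function(j) {
    xpt_namestr(j, toupper(names(df)[j]), is_char[j], widths[j], pos[j])
  }))
  put(ns)
  pad <- (80 - length(ns) %% 80) %% 80
  if (pad > 0) puts(strrep(" ", pad))

  puts(xpt_header_record("OBS     "))
  nbytes <- 0
  for (i in seq_len(nrow(df))) {
    for (j in seq_along(df)) {
      bytes <- if (is_char[j]) {
        charToRaw(xpt_pad(df[[j]][i], widths[j]))
      } else {
        ieee_to_ibm(as.numeric(df[[j]][i]))
      }
      put(bytes)
      nbytes <- nbytes + length(bytes)
    }
  }
  pad <- (80 - nbytes %% 80) %% 80
  if (pad > 0) puts(strrep(" ", pad))
  invisible(path)
}
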