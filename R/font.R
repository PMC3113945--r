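# Built-in 5x7 bitmap font ("builtin5x7"): the only font the renderer ships.
# Deterministic by construction -- no platform font stack is involved.
# Lowercase input is drawn with the uppercase glyphs; unknown characters fall
# back to the '?' glyph. Advance is 6 px (5 px glyph + 1 px spacing).

FONT_DEF <- list(
  "A" = c(".XXX.","X...X","X...X","XXXXX","X...X","X...X","X...X"),
  "B" = c("XXXX.","X...X","X...X","XXXX.","X...X","X...X","XXXX."),
  "C" = c(".XXX.","X...X","X....","X....","X....","X...X",".XXX."),
  "D" = c("XXXX.","X...X","X...X","X...X","X...X","X...X","XXXX."),
  "E" = c("XXXXX","X....","X....","XXXX.","X....","X....","XXXXX"),
  "F" = c("XXXXX","X....","X....","XXXX.","X....","X....","X...."),
  "G" = c(".XXX.","X...X","X....","X.XXX","X...X","X...X",".XXX."),
  "H" = c("X...X","X...X","X...X","XXXXX","X...X","X...X","X...X"),
  "I" = c(".XXX.","..X..","..X..","..X..","..X..","..X..",".XXX."),
  "J" = c("..XXX","...X.","...X.","...X.","...X.","X..X.",".XX.."),
  "K" = c("X...X","X..X.","X.X..","XX...","X.X..","X..X.","X...X"),
  "L" = c("X....","X....","X....","X....","X....","X....","XXXXX"),
  "M" = c("X...X","XX.XX","X.X.X","X.X.X","X...X","X...X","X...X"),
  "N" = c("X...X","XX..X","X.X.X","X..XX","X...X","X...X","X...X"),
  "O" = c(".XXX.","X...X","X...X","X...X","X...X","X...X",".XXX."),
  "P" = c("XXXX.","X...X","X...X","XXXX.","X....","X....","X...."),
  "Q" = c(".XXX.","X...X","X...X","X...X","X.X.X","X..X.",".XX.X"),
  "R" = c("XXXX.","X...X","X...X","XXXX.","X.X..","X..X.","X...X"),
  "S" = c(".XXXX","X....","X....",".XXX.","....X","....X","XXXX."),
  "T" = c("XXXXX","..X..","..X..","..X..","..X..","..X..","..X.."),
  "U" = c("X...X","X...X","X...X","X...X","X...X","X...X",".XXX."),
  "V" = c("X...X","X...X","X...X","X...X","X...X",".X.X.","..X.."),
  "W" = c("X...X","X...X","X...X","X.X.X","X.X.X","XX.XX","X...X"),
  "X" = c("X...X","X...X",".X.X.","..X..",".X.X.","X...X","X...X"),
  "Y" = c("X...X","X...X",".X.X.","..X..","..X..","..X..","..X.."),
  "Z" = c("XXXXX","....X","...X.","..X..",".X...","X....","XXXXX"),
  "0" = c(".XXX.","X...X","X..XX","X.X.X","XX..X","X...X",".XXX."),
  "1" = c("..X..",".XX..","..X..","..X..","..X..","..X..",".XXX."),
  "2" = c(".XXX.","X...X","....X","...X.","..X..",".X...","XXXXX"),
  "3" = c("XXXXX","....X","...X.","..XX.","....X","X...X",".XXX."),
  "4" = c("...X.","..XX.",".X.X.","X..X.","XXXXX","...X.","...X."),
  "5" = c("XXXXX","X....","XXXX.","....X","....X","X...X",".XXX."),
  "6" = c("..XX.",".X...","X....","XXXX.","X...X","X...X",".XXX."),
  "7" = c("XXXXX","....X","...X.","..X..",".X...",".X...",".X..."),
  "8" = c(".XXX.","X...X","X...X",".XXX.","X...X","X...X",".XXX."),
  "9" = c(".XXX.","X...X","X...X",".XXXX","....X","...X.",".XX.."),
  "-" = c(".....",".....",".....","XXXXX",".....",".....","....."),
  "+" = c(".....","..X..","..X..","XXXXX","..X..","..X..","....."),
  "." = c(".....",".....",".....",".....",".....","..X..","..X.."),
  "," = c(".....",".....",".....",".....","..X..","..X..",".X..."),
  ":" = c(".....","..X..","..X..",".....","..X..","..X..","....."),
  "_" = c(".....",".....",".....",".....",".....",".....","XXXXX"),
  "/" = c("....X","....X","...X.","..X..",".X...","X....","X...."),
  "(" = c("...X.","..X..",".X...",".X...",".X...","..X..","...X."),
  ")" = c(".X...","..X..","...X.","...X.","...X.","..X..",".X..."),
  "'" = c("..X..","..X..",".....",".....",".....",".....","....."),
  "?" = c(".XXX.","X...X","....X","...X.","..X..",".....","..X.."),
  " " = c(".....",".....",".....",".....",".....",".....",".....")
)

# each glyph as a 7x5 logical matrix
FONT5X7 <- local({
  glyphs <- lapply(FONT_DEF, function(rows)
    t(vapply(rows, function(r) strsplit(r, "")[[1]] == "X", logical(5))))
  list(name = "builtin5x7", glyphs = glyphs, width = 5L, height = 7L, advance = 6L)
})

textChars <- function(text, font = FONT5X7) {
  ch <- toupper(strsplit(text, "")[[1]])
  ch[!ch %in% names(font$glyphs)] <- "?"
  ch
}

# rendered pixel width of a string (no trailing spacing column)
textWidth <- function(text, font = FONT5X7) {
  n <- nchar(text)
  if (n == 0) return(0L)
  n * font$advance - 1L
}
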