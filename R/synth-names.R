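# Name and municipality pools for the synthetic cohort generator.
# Brazilian-style given names and surnames, kept in their accented raw
# forms so that generated files exercise the accent-stripping and casing
# rules of harmonization. Not a demographic model; just plausible shapes.

.synth_given_female <- c(
  "MARIA", "ANA", "FRANCISCA", "ANTÔNIA", "ADRIANA", "JULIANA", "MÁRCIA",
  "FERNANDA", "PATRÍCIA", "ALINE", "SANDRA", "CAMILA", "AMANDA", "BRUNA",
  "JESSICA", "LETÍCIA", "JÚLIA", "LUCIANA", "VANESSA", "MARIANA", "GABRIELA",
  "VERA", "VITÓRIA", "LARISSA", "CLÁUDIA", "BEATRIZ", "LUANA", "RAFAELA",
  "ROSÂNGELA", "APARECIDA", "CONCEIÇÃO", "TEREZINHA", "SEBASTIANA", "JOANA",
  "CRISTIANE", "DANIELA", "TATIANE", "SIMONE", "MICHELE", "ELAINE",
  "ROSA", "HELENA", "LUZIA", "IVONE", "NEUSA", "CECÍLIA", "EDNA", "SÔNIA",
  "REGINA", "FÁTIMA", "LÚCIA", "RITA", "MADALENA", "GLÓRIA", "INÊS",
  "DAS DORES", "SOCORRO", "LOURDES", "ISABEL", "CAROLINA"
)

.synth_given_male <- c(
  "JOSÉ", "JOÃO", "ANTÔNIO", "FRANCISCO", "CARLOS", "PAULO", "PEDRO",
  "LUCAS", "LUIZ", "MARCOS", "LUIS", "GABRIEL", "RAFAEL", "DANIEL",
  "MARCELO", "BRUNO", "EDUARDO", "FELIPE", "RAIMUNDO", "RODRIGO",
  "MANOEL", "MATEUS", "ANDRÉ", "FERNANDO", "FÁBIO", "LEONARDO", "GUSTAVO",
  "GUILHERME", "LEANDRO", "TIAGO", "SEBASTIÃO", "ROBERTO", "RICARDO",
  "ALEXANDRE", "EDSON", "GERALDO", "ADRIANO", "VINÍCIUS", "JORGE",
  "DIEGO", "MAURO", "SÉRGIO", "CLÁUDIO", "RENATO", "WELLINGTON", "OTÁVIO",
  "JOAQUIM", "BENEDITO", "DOMINGOS", "SAMUEL", "CÍCERO", "AUGUSTO",
  "EVERTON", "JAIR", "WILSON", "OSVALDO", "NELSON", "IVAN", "HUGO", "CAIO"
)

.synth_surnames <- c(
  "SILVA", "SANTOS", "OLIVEIRA", "SOUZA", "RODRIGUES", "FERREIRA", "ALVES",
  "PEREIRA", "LIMA", "GOMES", "COSTA", "RIBEIRO", "MARTINS", "CARVALHO",
  "ALMEIDA", "LOPES", "SOARES", "FERNANDES", "VIEIRA", "BARBOSA", "ROCHA",
  "DIAS", "NASCIMENTO", "ANDRADE", "MOREIRA", "NUNES", "MARQUES", "MACHADO",
  "MENDES", "FREITAS", "CARDOSO", "RAMOS", "GONÇALVES", "SANTANA", "TEIXEIRA",
  "ARAÚJO", "PINTO", "CORREIA", "MONTEIRO", "CAVALCANTI", "MOURA", "BATISTA",
  "BEZERRA", "MIRANDA", "CAMPOS", "DUARTE", "BORGES", "MELO", "CASTRO",
  "AZEVEDO", "BARROS", "REIS", "MORAES", "MEDEIROS", "MAGALHÃES", "NOGUEIRA",
  "FARIAS", "TAVARES", "AGUIAR", "XAVIER", "SALES", "PAIVA", "BRITO",
  "GUIMARÃES", "QUEIROZ", "ASSIS", "SIQUEIRA", "VASCONCELOS", "FOGAÇA",
  "DA CRUZ", "DA LUZ", "DA PAZ", "DO NASCIMENTO", "DE JESUS", "DOS ANJOS"
)

# Municipality codes shaped like 7-digit IBGE codes (2-digit state prefix
# plus 5 digits); a small fixed pool so blocks form naturally.
.synth_municipalities <- function(n_pool = 40L) {
  states <- c(11, 17, 21, 23, 26, 29, 31, 33, 35, 41, 43, 50, 52)
  sprintf("%02d%05d", sample(states, n_pool, replace = TRUE),
          sample.int(99999L, n_pool))
}
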