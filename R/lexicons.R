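# Small in-repo lexicons for the synthetic population generator. These are
# invented but plausible Australian-flavoured name/address pools; no
# external data is downloaded. Diminutive pairs drive the alternate-form
# first-name corruption (ELIZABETH -> LIZ and similar).

.given_female <- c(
  "ELIZABETH", "MARGARET", "KATHERINE", "VICTORIA", "STEPHANIE", "SAMANTHA",
  "JESSICA", "REBECCA", "CHARLOTTE", "AMELIA", "OLIVIA", "SOPHIE", "EMILY",
  "HANNAH", "GRACE", "CHLOE", "LUCY", "RUBY", "ISABELLA", "MIA", "EVELYN",
  "PATRICIA", "JENNIFER", "LINDA", "BARBARA", "SUSAN", "DOROTHY", "SARAH",
  "KIMBERLY", "DEBORAH", "LAURA", "CYNTHIA", "KATHLEEN", "AMANDA", "MELISSA",
  "MICHELLE", "CAROLYN", "JANET", "CATHERINE", "FRANCES", "CHRISTINE",
  "JOSEPHINE", "ALEXANDRA", "VERONICA", "PENELOPE", "ROSEMARY", "THERESA",
  "JACQUELINE", "GABRIELLA", "NATALIE", "IRENE", "AUDREY", "BEVERLEY",
  "GWENDOLYN", "HENRIETTA", "MADELINE", "CLEMENTINE", "FELICITY", "HARRIET",
  "IMOGEN", "LAVINIA", "MIRANDA", "PRUDENCE", "ROSALIND", "TABITHA",
  "URSULA", "WINIFRED", "YVONNE", "ZOE", "BRIDGET"
)

.given_male <- c(
  "WILLIAM", "JONATHAN", "CHRISTOPHER", "ALEXANDER", "BENJAMIN", "NICHOLAS",
  "MATTHEW", "ANDREW", "DANIEL", "MICHAEL", "THOMAS", "JOSHUA", "SAMUEL",
  "JACOB", "ETHAN", "NOAH", "OLIVER", "HENRY", "CHARLES", "GEORGE", "JAMES",
  "ROBERT", "JOHN", "DAVID", "RICHARD", "JOSEPH", "EDWARD", "ANTHONY",
  "STEVEN", "KENNETH", "GREGORY", "PATRICK", "RAYMOND", "LAWRENCE",
  "FREDERICK", "HAROLD", "DOUGLAS", "RONALD", "GERALD", "TIMOTHY",
  "SEBASTIAN", "THEODORE", "NATHANIEL", "ZACHARY", "DOMINIC", "VINCENT",
  "MALCOLM", "DESMOND", "RUPERT", "BARNABY", "CORNELIUS", "EUGENE",
  "FERDINAND", "GILBERT", "HORACE", "IGNATIUS", "LEOPOLD", "MONTGOMERY",
  "NORMAN", "OSWALD", "PERCIVAL", "QUENTIN", "RODERICK", "STANLEY",
  "TREVOR", "VERNON", "WALLACE", "XAVIER", "ARCHIBALD", "BERNARD"
)

# canonical form -> diminutive
.diminutives <- c(
  ELIZABETH = "LIZ", MARGARET = "PEGGY", KATHERINE = "KATE",
  VICTORIA = "VICKY", STEPHANIE = "STEPH", SAMANTHA = "SAM",
  JESSICA = "JESS", REBECCA = "BECKY", CHARLOTTE = "LOTTIE",
  PATRICIA = "TRISH", JENNIFER = "JENNY", DEBORAH = "DEBBIE",
  KIMBERLY = "KIM", AMANDA = "MANDY", MICHELLE = "SHELLEY",
  JACQUELINE = "JACKIE", JOSEPHINE = "JO", ALEXANDRA = "SANDY",
  WILLIAM = "BILL", JONATHAN = "JON", CHRISTOPHER = "CHRIS",
  ALEXANDER = "ALEX", BENJAMIN = "BEN", NICHOLAS = "NICK",
  MATTHEW = "MATT", ANDREW = "ANDY", DANIEL = "DAN", MICHAEL = "MICK",
  THOMAS = "TOM", JOSHUA = "JOSH", SAMUEL = "SAM", JACOB = "JAKE",
  ROBERT = "BOB", JOHN = "JACK", RICHARD = "DICK", JOSEPH = "JOE",
  EDWARD = "TED", ANTHONY = "TONY", STEVEN = "STEVE", GREGORY = "GREG",
  PATRICK = "PADDY", FREDERICK = "FRED", TIMOTHY = "TIM",
  THEODORE = "THEO", ZACHARY = "ZACH", DOMINIC = "DOM"
)

.surnames <- c(
  "SMITH", "JONES", "WILLIAMS", "BROWN", "WILSON", "TAYLOR", "JOHNSON",
  "WHITE", "MARTIN", "ANDERSON", "THOMPSON", "NGUYEN", "THOMAS", "WALKER",
  "HARRIS", "LEE", "RYAN", "ROBINSON", "KELLY", "KING", "DAVIS", "WRIGHT",
  "EVANS", "ROBERTS", "GREEN", "HALL", "WOOD", "JACKSON", "CLARKE",
  "PATEL", "KHAN", "LEWIS", "JAMES", "PHILLIPS", "MASON", "MITCHELL",
  "ROSE", "DAVIES", "RODRIGUEZ", "COX", "ALEXANDER", "GARDEN", "CAMPBELL",
  "JOHNSTON", "MOORE", "SINGH", "SCOTT", "MCDONALD", "STEWART", "MURPHY",
  "CAMERON", "COLLINS", "BELL", "COOPER", "HUGHES", "BAKER", "CARTER",
  "RICHARDSON", "BAILEY", "REID", "GRAHAM", "HAMILTON", "GRANT",
  "FERGUSON", "MURRAY", "HENDERSON", "FRASER", "ROSS", "KENNEDY",
  "SIMPSON", "MARSHALL", "HARRISON", "PEARSON", "FITZGERALD",
  "SULLIVAN", "BYRNE", "GALLAGHER", "DOHERTY", "BRENNAN", "BURKE",
  "MOLONEY", "WHELAN", "CONNOLLY", "HOGAN", "DUFFY", "MAGUIRE",
  "KAUR", "CHEN", "WANG", "LIU", "ZHANG", "TRAN", "PHAM", "LIM",
  "TAN", "WONG", "HO", "PAPADOPOULOS", "ROSSI", "RUSSO", "FERRARI",
  "ESPOSITO", "ROMANO", "COSTA", "SILVA", "SANTOS", "PEREIRA",
  "KOWALSKI", "NOWAK", "IVANOV", "PETROV", "SCHMIDT", "MUELLER",
  "WEBER", "WAGNER", "BECKER", "HOFFMANN", "ANDERSSON", "JOHANSSON",
  "LINDQVIST", "HANSEN"
)

.streets <- c(
  "JOHN", "GEORGE", "KING", "QUEEN", "VICTORIA", "ALBERT", "STATION",
  "CHURCH", "HIGH", "MAIN", "PARK", "BEACH", "FOREST", "RIVER", "LAKE",
  "HILL", "VALLEY", "ORCHARD", "GARDEN", "MEADOW", "SPRING", "SUMMER",
  "WATTLE", "BANKSIA", "ACACIA", "EUCALYPT", "JARRAH", "KARRI", "MARRI",
  "TUART", "BOAB", "MULGA", "SHEOAK", "CASUARINA", "GREVILLEA", "HAKEA",
  "MELALEUCA", "CORREA", "BORONIA", "KANGAROO", "EMU", "SWAN", "PELICAN",
  "IBIS", "HERON", "FALCON", "KESTREL", "OSPREY", "CURLEW", "BRONZEWING"
)

.street_types <- c("ST", "RD", "AVE", "CRES", "WAY", "CT", "PL", "DR")

.facilities <- c(
  "ACME AGED CARE HOME", "ST LUKES NURSING HOME", "RIVERSIDE HOSTEL",
  "SUNSET LODGE", "HILLVIEW CARE CENTRE", "WARATAH HOUSE"
)

.placeholder_addresses <- c("NO FIXED ADDRESS", "UNKNOWN")
.placeholder_postcodes <- c("9999", "0000")

.suburbs <- data.frame(
  suburb = c(
    "PERTH", "FREMANTLE", "SUBIACO", "CLAREMONT", "NEDLANDS", "BENTLEY",
    "CANNINGTON", "ARMADALE", "MIDLAND", "GUILDFORD", "BASSENDEAN",
    "MORLEY", "SCARBOROUGH", "KARRINYUP", "JOONDALUP", "WANNEROO",
    "ROCKINGHAM", "MANDURAH", "KWINANA", "COCKBURN", "MELVILLE",
    "APPLECROSS", "SOUTH PERTH", "VICTORIA PARK", "BELMONT", "KALAMUNDA",
    "MUNDARING", "GOSNELLS", "THORNLIE", "WILLETTON", "BUNBURY",
    "BUSSELTON", "ALBANY", "GERALDTON", "KALGOORLIE", "BROOME",
    "KARRATHA", "PORT HEDLAND", "ESPERANCE", "NORTHAM"
  ),
  postcode = c(
    "6000", "6160", "6008", "6010", "6009", "6102",
    "6107", "6112", "6056", "6055", "6054",
    "6062", "6019", "6018", "6027", "6065",
    "6168", "6210", "6167", "6164", "6156",
    "6153", "6151", "6100", "6104", "6076",
    "6073", "6110", "6108", "6155", "6230",
    "6280", "6330", "6530", "6430", "6725",
    "6714", "6721", "6450", "6401"
  ),
  stringsAsFactors = FALSE
)
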