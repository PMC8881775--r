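{
  "categories": {
    "i": ["ik", "mij", "mijn", "me", "mezelf", "ikzelf", "mijzelf", "m'n"],
    "we": ["we", "wij", "ons", "onze", "onszelf", "wijzelf", "samen"],
    "you": ["je", "jij", "jou", "jouw", "jullie", "jezelf", "u", "uw"],
    "negate": ["niet", "geen", "nooit", "niets", "niks", "nee", "noch", "zonder", "nergens", "niemand", "nimmer"],
    "posemo": ["blij", "goed", "fijn", "leuk", "mooi", "lief", "gelukkig*", "super", "top", "geweldig", "prettig", "tevreden", "trots", "plezier", "vrolijk*", "geniet*", "liefde", "dankbaar", "fantastisch", "heerlijk", "prima", "gezellig*", "lach*", "fijne", "goede", "leuke", "mooie", "lieve"],
    "negemo": ["slecht", "rot", "vervelend", "verdriet*", "boos", "bang", "somber", "ellendig", "pijn", "jammer", "vreselijk", "verschrikkelijk", "teleurgesteld", "eenzaam", "gestrest", "onrustig", "zwaar", "stom", "balen", "akelig", "erg", "erge"],
    "anx": ["bang", "angst*", "nerveus", "zenuwachtig", "gespannen", "onzeker", "paniek*", "vrees", "zorgen", "ongerust", "spanning", "stress", "gestrest"],
    "anger": ["boos", "kwaad", "woede", "woedend", "geirriteerd", "irritant", "frustratie", "gefrustreerd", "razend", "ergernis", "erger*", "haat", "woest"],
    "sad": ["verdriet*", "somber", "huil*", "depressief", "droevig", "treurig", "eenzaam", "gemis", "rouw", "neerslachtig", "wanhopig"],
    "certain": ["zeker", "altijd", "nooit", "absoluut", "helemaal", "compleet", "totaal", "echt", "duidelijk", "precies", "vast", "beslist", "uiteraard", "natuurlijk"],
    "swear": ["verdomme", "shit", "fuck", "kut", "damn", "godver*", "klote", "verdorie", "dammit"]
  },
  "emoji": {
    "positive": [":)", ":-)", ":D", ":-D", ";)", ";-)", "<3", "😊", "😀", "😁", "🙂", "❤"],
    "negative": [":(", ":-(", ":'(", ":/", "</3", "😢", "😠", "☹", "😞"]
  }
}
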