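{
  "schema_id": "cuestionario_es_v1",
  "language": "es",
  "topics": [
    {
      "topic_id": "personal_information",
      "title": "Información personal",
      "questions": [
        {"slot_name": "patient_name", "prompt_text": "¿Cuál es el nombre de la persona?", "value_kind": "free_text", "required": true, "context": "pwad_profile"},
        {"slot_name": "apodo", "prompt_text": "¿Tiene algún apodo o diminutivo con el que le gusta que le llamen?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "fecha_nacimiento", "prompt_text": "¿Cuál es su fecha de nacimiento?", "value_kind": "date", "required": false, "context": "pwad_profile"},
        {"slot_name": "lugar_nacimiento", "prompt_text": "¿En qué lugar nació?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "edad", "prompt_text": "¿Qué edad tiene?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "genero", "prompt_text": "¿Cuál es su género?", "value_kind": "enum", "required": false, "context": "pwad_profile", "choices": ["femenino", "masculino", "otro"]},
        {"slot_name": "estado_civil", "prompt_text": "¿Cuál es su estado civil?", "value_kind": "enum", "required": false, "context": "pwad_profile", "choices": ["soltera/o", "casada/o", "viuda/o", "divorciada/o"]},
        {"slot_name": "profesion", "prompt_text": "¿A qué se dedicó la mayor parte de su vida?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "religion", "prompt_text": "¿Profesa alguna religión?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "color_favorito", "prompt_text": "¿Cuál es su color favorito?", "value_kind": "free_text", "required": false, "context": "pwad_profile"},
        {"slot_name": "descripcion_lugar_nacimiento", "prompt_text": "Describa brevemente algo que le gusta de su lugar de nacimiento.", "value_kind": "free_text", "required": false, "context": "visited_places"}
      ]
    },
    {
      "topic_id": "family_relationships",
      "title": "Relaciones familiares",
      "questions": [
        {"slot_name": "nombre_conyuge", "prompt_text": "¿Cómo se llama (o llamaba) su cónyuge o pareja?", "value_kind": "free_text", "required": false, "context": "family"},
        {"slot_name": "numero_hijos", "prompt_text": "¿Cuántos hijos tiene?", "value_kind": "free_text", "required": false, "context": "family"},
        {"slot_name": "familiar_mas_cercano", "prompt_text": "¿Quién es el familiar con quien más convive?", "value_kind": "free_text", "required": false, "context": "family"},
        {"slot_name": "recuerdo_familiar", "prompt_text": "Mencione un recuerdo agradable en familia.", "value_kind": "free_text", "required": false, "context": "family"}
      ]
    },
    {
      "topic_id": "life_history_lifestyle",
      "title": "Historia de vida y estilo de vida",
      "questions": [
        {"slot_name": "habito_diario", "prompt_text": "¿Qué hábito diario disfrutaba realizar?", "value_kind": "free_text", "required": false, "context": "habits"},
        {"slot_name": "rutina_diaria", "prompt_text": "Describa brevemente su rutina de un día normal.", "value_kind": "free_text", "required": false, "context": "habits"},
        {"slot_name": "habilidad", "prompt_text": "¿En qué actividad era especialmente buena/o (tejer, dibujar, cantar, carpintería)?", "value_kind": "free_text", "required": false, "context": "skills"},
        {"slot_name": "hobby", "prompt_text": "¿Cuál es su pasatiempo preferido?", "value_kind": "free_text", "required": false, "context": "hobbies"},
        {"slot_name": "labor_hogar", "prompt_text": "¿Con qué actividad del hogar disfrutaba ayudar?", "value_kind": "free_text", "required": false, "context": "household_chores"},
        {"slot_name": "lugar_visitado", "prompt_text": "¿Qué lugar visitado fue importante en su vida?", "value_kind": "free_text", "required": false, "context": "visited_places"},
        {"slot_name": "recuerdo_infancia", "prompt_text": "Mencione algún recuerdo agradable de su infancia.", "value_kind": "free_text", "required": false, "context": "visited_places"},
        {"slot_name": "pelicula_favorita", "prompt_text": "¿Cuál es su película favorita?", "value_kind": "free_text", "required": false, "context": "movies"},
        {"slot_name": "programa_tv", "prompt_text": "¿Cuál es su programa de televisión favorito?", "value_kind": "free_text", "required": false, "context": "tv_shows"},
        {"slot_name": "actor_favorito", "prompt_text": "¿Qué actor, actriz o personaje le interesa más?", "value_kind": "free_text", "required": false, "context": "actors"},
        {"slot_name": "musica_favorita", "prompt_text": "¿Qué tipo de música prefiere?", "value_kind": "free_text", "required": false, "context": "music"},
        {"slot_name": "cantante_favorito", "prompt_text": "¿Qué cantante o grupo musical prefiere?", "value_kind": "free_text", "required": false, "context": "singers"},
        {"slot_name": "deporte_favorito", "prompt_text": "¿Qué deporte prefiere?", "value_kind": "free_text", "required": false, "context": "sports"},
        {"slot_name": "equipo_favorito", "prompt_text": "¿Qué equipo o deportista es relevante para usted?", "value_kind": "free_text", "required": false, "context": "sport_teams"},
        {"slot_name": "comida_favorita", "prompt_text": "¿Cuál es su platillo favorito?", "value_kind": "free_text", "required": false, "context": "food_dishes"},
        {"slot_name": "bebida_favorita", "prompt_text": "¿Cuál es su bebida favorita?", "value_kind": "free_text", "required": false, "context": "beverages"},
        {"slot_name": "festividad_favorita", "prompt_text": "¿Qué festividad le gusta más?", "value_kind": "free_text", "required": false, "context": "festivities"}
      ]
    }
  ]
}
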