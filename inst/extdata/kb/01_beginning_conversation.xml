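<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="beginning_conversation" description="opening greetings for the patient">
  <category entry="true">
    <pattern>hola</pattern>
    <template><random><li><condition name="patient_name"><li value="present">¡Hola <get name="patient_name"/>! ¿Cómo te sientes el día de hoy?</li><li>¡Hola! ¿Cómo te sientes el día de hoy?</li></condition></li><li><condition name="patient_name"><li value="present">¡Hola <get name="patient_name"/>! Qué gusto saludarte. ¿Cómo estás hoy?</li><li>¡Hola! Qué gusto saludarte. ¿Cómo estás hoy?</li></condition></li></random></template>
  </category>
  <category>
    <pattern>hola *</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>* hola</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>buenos días</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>buenos días *</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>buenos dias</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>buenas tardes</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>buenas noches</pattern>
    <template><srai>hola</srai></template>
  </category>
  <category>
    <pattern>bien</pattern>
    <template><random><li>¡Qué gusto! ¿Te gustaría platicar un rato conmigo?</li><li>Me alegra mucho. ¿Platicamos un poco?</li></random></template>
  </category>
  <category>
    <pattern>bien *</pattern>
    <template><srai>bien</srai></template>
  </category>
  <category>
    <pattern>* bien</pattern>
    <template><srai>bien</srai></template>
  </category>
  <category>
    <pattern>* bien *</pattern>
    <template><srai>bien</srai></template>
  </category>
  <category>
    <pattern>mal</pattern>
    <template><random><li>Lo siento mucho. ¿Te gustaría platicar un rato para distraerte?</li><li>Qué pena. ¿Quieres que platiquemos de algo bonito?</li></random></template>
  </category>
  <category>
    <pattern>mal *</pattern>
    <template><srai>mal</srai></template>
  </category>
  <category>
    <pattern>* mal</pattern>
    <template><srai>mal</srai></template>
  </category>
  <category>
    <pattern>* mal *</pattern>
    <template><srai>mal</srai></template>
  </category>
  <category>
    <pattern>sí</pattern>
    <template><random><li>¡Muy bien! ¿De qué te gustaría platicar hoy?</li><li>¡Qué bien! ¿Qué tema te gustaría recordar hoy?</li></random></template>
  </category>
  <category>
    <pattern>sí *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* sí</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>no</pattern>
    <template><random><li>Está bien. ¿De qué otra cosa te gustaría platicar?</li><li>No hay problema. ¿Hay otro tema que te guste más?</li></random></template>
  </category>
  <category>
    <pattern>no *</pattern>
    <template><srai>no</srai></template>
  </category>
  <category fallback="true">
    <pattern>fallback</pattern>
    <template><random><li>Entiendo. ¿Me cuentas un poco más?</li><li>Ya veo. ¿Qué más recuerdas de eso?</li></random></template>
  </category>
</topic>
</aiml>
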